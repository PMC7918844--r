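## Independent oracles used across the test files.  These deliberately
## avoid the package's own evaluation paths.

## J1 by its ascending power series: sum_k (-1)^k (x/2)^(2k+1) / (k! (k+1)!)
j1_power_series <- function(x) {
  term <- x / 2
  total <- term
  k <- 0
  while (abs(term) > 1e-18) {
    k <- k + 1
    term <- -term * (x / 2)^2 / (k * (k + 1))
    total <- total + term
  }
  total
}

## plain bisection
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  stopifnot(flo * f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

## brute-force trapezoid evaluation of the isolated-disk Hankel integral
## on y in [0, y_max] (finite-cutoff reference for the oscillation-aware
## quadrature)
trapezoid_disk_potential <- function(x, rho, lam, eta, y_max = 400,
                                     n = 2e6) {
  y <- seq(1e-9, y_max, length.out = n)
  fy <- besselJ(y * x, 0) * besselJ(y * rho, 1) /
    (sqrt((lam * y)^2 + 1) + eta * lam * y)
  sum((fy[-1] + fy[-n]) / 2) * (y[2] - y[1]) / rho
}

## common fixtures
medium_unit <- function(eta = 1) electrolyte_interface(lD = 1, eps_ratio = eta)
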