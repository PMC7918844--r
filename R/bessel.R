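## Bessel-function basis: J0/J1 evaluation safe at large argument, ordered
## zeros of J1, and the Fourier-Bessel coefficients of the step charge
## density.

## base::besselJ overflows its internal workspace for x beyond ~1e5; the
## zero tables used by the free-energy sweeps reach far past that, so
## large arguments are evaluated with the Hankel asymptotic expansion
## (accurate to ~1e-15 for x > 500 at orders 0 and 1).
.bessel_j <- function(x, nu) {
  out <- numeric(length(x))
  big <- x > 500
  if (any(!big)) out[!big] <- besselJ(x[!big], nu)
  if (any(big)) {
    xb <- x[big]
    mu <- 4 * nu^2
    z8 <- 1 / (8 * xb)
    P <- 1 - (mu - 1) * (mu - 9) / 2 * z8^2 +
      (mu - 1) * (mu - 9) * (mu - 25) * (mu - 49) / 24 * z8^4
    Q <- (mu - 1) * z8 - (mu - 1) * (mu - 9) * (mu - 25) / 6 * z8^3
    chi <- xb - (nu / 2 + 0.25) * pi
    out[big] <- sqrt(2 / (pi * xb)) * (P * cos(chi) - Q * sin(chi))
  }
  out
}

## positive zeros of J_nu, nu in {0, 1}; vectorized Newton refinement from
## the McMahon asymptotic seeds, cached and grown on demand.  The final
## residual check guarantees the advertised 1e-12 contract.
.bessel_zeros <- function(n, nu) {
  key <- paste0("z", nu)
  have <- get0(key, envir = .dh_cache)
  if (!is.null(have) && length(have) >= n) return(have[seq_len(n)])
  x <- (seq_len(n) + nu / 2 - 0.25) * pi
  x <- x - (4 * nu^2 - 1) / (8 * x)   # first McMahon correction
  for (it in 1:60) {
    f <- .bessel_j(x, nu)
    df <- if (nu == 1) .bessel_j(x, 0) - f / x else -.bessel_j(x, 1)
    dx <- f / df
    x <- x - dx
    if (max(abs(dx)) < 1e-13) break
  }
  if (max(abs(.bessel_j(x, nu))) > 1e-12) {
    stop("Bessel zero refinement failed to reach the 1e-12 residual contract")
  }
  assign(key, x, envir = .dh_cache)
  x
}

.zeros_j1 <- function(n) .bessel_zeros(n, 1L)
.zeros_j0 <- function(n) .bessel_zeros(n, 0L)

#' Ordered zeros of the Bessel function J1
#'
#' Returns \eqn{y_0 = 0 < y_1 < y_2 < \dots < y_{n_{max}}} with
#' \eqn{J_1(y_n) = 0}.  These are the radial wavenumbers of the
#' Fourier-Bessel modes \eqn{J_0(y_n r/R)} whose radial derivative vanishes
#' at the Wigner-Seitz cell boundary \eqn{r = R}.  The table is cached, so
#' repeated calls (and internal series evaluations) reuse it; recomputation
#' is bitwise reproducible.
#'
#' @param n_max non-negative integer; the table holds `n_max + 1` entries
#'   including the leading exact zero.
#' @return an object of class `bessel_zero_table`: a list with elements
#'   `zeros` (numeric vector) and `n_max`.
#' @examples
#' j1_zeros(3)$zeros  # 0, 3.8317..., 7.0156..., 10.1735...
#' @export
j1_zeros <- function(n_max) {
  if (!(length(n_max) == 1 && is.numeric(n_max) && !is.na(n_max) &&
          n_max >= 0 && n_max == floor(n_max))) {
    stop("'n_max' must be a single non-negative integer")
  }
  zeros <- if (n_max == 0) 0 else c(0, .zeros_j1(n_max))
  structure(list(zeros = zeros, n_max = as.integer(n_max)),
            class = "bessel_zero_table")
}

#' @export
print.bessel_zero_table <- function(x, ...) {
  cat("Zeros of J1: y_0 ... y_", x$n_max, "\n", sep = "")
  print(utils::head(x$zeros, 8), ...)
  if (x$n_max > 7) cat("... (", x$n_max + 1, " entries)\n", sep = "")
  invisible(x)
}

#' Fourier-Bessel coefficients of the step charge density
#'
#' For the step profile that condenses the cell charge
#' \eqn{\sigma_0 \pi R^2} into a concentric disk of radius \eqn{r_0}
#' (density \eqn{\bar\sigma = \sigma_0 R^2/r_0^2} inside, zero outside),
#' the expansion \eqn{\sigma(r) = \sum_n \sigma_n J_0(y_n r/R)} has
#' \eqn{\sigma_0/\sigma_0 = 1} and, for \eqn{n \ge 1},
#' \deqn{\sigma_n/\sigma_0 = \frac{2R}{r_0}\,
#'   \frac{J_1(y_n r_0/R)}{y_n [J_0(y_n)]^2}.}
#'
#' @param r0_over_R disk-to-cell radius ratio in (0, 1].  The point-charge
#'   case is handled analytically elsewhere, never by `r0_over_R = 0` here.
#' @param n_max highest mode index; the return value has `n_max + 1`
#'   entries.
#' @return numeric vector of scaled coefficients \eqn{\sigma_n/\sigma_0},
#'   first entry exactly 1.
#' @examples
#' sigma_coefficients(1, 4)    # uniform charge: all higher modes vanish
#' sigma_coefficients(0.4, 2)
#' @export
sigma_coefficients <- function(r0_over_R, n_max) {
  if (!(length(r0_over_R) == 1 && is.numeric(r0_over_R) &&
          !is.na(r0_over_R) && r0_over_R > 0 && r0_over_R <= 1)) {
    stop("'r0_over_R' must lie in (0, 1]")
  }
  if (!(length(n_max) == 1 && is.numeric(n_max) && n_max >= 0 &&
          n_max == floor(n_max))) {
    stop("'n_max' must be a single non-negative integer")
  }
  if (n_max == 0) return(1)
  yn <- .zeros_j1(n_max)
  c(1, (2 / r0_over_R) * .bessel_j(yn * r0_over_R, 1) /
      (yn * .bessel_j(yn, 0)^2))
}
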