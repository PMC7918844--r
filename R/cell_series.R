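## Fourier-Bessel series solutions inside the Wigner-Seitz cell.
##
## Every mode n >= 1 of the surface potential carries the denominator
##   g(y) = sqrt((lD y / R)^2 + 1) + (eps_l/eps_w) (lD/R) y,
## the scaled version of eps_w*sqrt(k^2 + 1/lD^2) + eps_l*k that the
## dielectric-jump boundary condition imposes on each radial wavenumber.

.mode_denominator <- function(y, lam, eta) {
  sqrt((lam * y)^2 + 1) + eta * lam * y
}

## shared evaluation of  1 + sum_n w_n J0(y_n x)  on a grid, fixed order
.cell_series_sum <- function(x, weights, yn) {
  vapply(x, function(xi) 1 + sum(weights * .bessel_j(yn * xi, 0)), 0)
}

## adaptive doubling of n_max until the profile stops changing
.cell_series_adaptive <- function(x, weight_fun, rel_tol,
                                  n_start = 512L, n_cap = 262144L) {
  n <- n_start
  yn <- .zeros_j1(n)
  v <- .cell_series_sum(x, weight_fun(yn), yn)
  repeat {
    n2 <- 2L * n
    yn <- .zeros_j1(n2)
    v2 <- .cell_series_sum(x, weight_fun(yn), yn)
    if (max(abs(v2 - v)) < rel_tol * max(1, max(abs(v2)))) {
      return(list(value = v2, n_max = n2))
    }
    v <- v2
    n <- n2
    if (n >= n_cap) {
      warning("series truncation cap reached before requested tolerance")
      return(list(value = v, n_max = n))
    }
  }
}

#' Scaled surface charge density inside the cell
#'
#' Partial sum of the Fourier-Bessel series for the step charge profile:
#' \eqn{\sigma(r)/\sigma_0 \to R^2/r_0^2} inside the disk, 0 outside, and
#' (by the Heaviside half-value convention) the midpoint
#' \eqn{R^2/(2 r_0^2)} at the step \eqn{r = r_0}.  The series converges
#' only conditionally (Gibbs oscillations at the step), so the default
#' truncation is a fixed `n_max = 4000` rather than the adaptive rule used
#' for the potential.
#'
#' @param r_over_R radii (vectorized), each in [0, 1].
#' @param geom a [cell_geometry()].
#' @param ctrl a [series_control()]; `ctrl$n_max = NULL` selects the fixed
#'   default 4000.
#' @return numeric vector of \eqn{\sigma(r)/\sigma_0} partial sums.
#' @examples
#' g <- cell_geometry(R = 1, r0 = 0.4)
#' sigma_profile(c(0, 0.4, 0.9), g)  # ~6.25, ~3.125 (midpoint), ~0
#' @export
sigma_profile <- function(r_over_R, geom, ctrl = series_control()) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(ctrl, "series_control"))
  if (any(r_over_R < 0 | r_over_R > 1)) stop("'r_over_R' must lie in [0, 1]")
  rho <- geom$r0_over_R
  n_max <- if (is.null(ctrl$n_max)) 4000L else ctrl$n_max
  cn <- sigma_coefficients(rho, n_max)[-1]
  yn <- .zeros_j1(n_max)
  .cell_series_sum(r_over_R, cn, yn)
}

#' Scaled surface potential of a charged disk inside the cell
#'
#' Evaluates
#' \deqn{\frac{\Phi_s(r)}{\Phi_0} = 1 + \sum_{n\ge1}
#'   \frac{J_0(y_n r/R)}{g(y_n)}\,
#'   \frac{2R}{r_0}\frac{J_1(y_n r_0/R)}{y_n [J_0(y_n)]^2},}
#' with \eqn{g(y) = \sqrt{(y\,l_D/R)^2 + 1} +
#' (\epsilon_l/\epsilon_w)(l_D/R)\,y} and
#' \eqn{\Phi_0 = \sigma_0 l_D/(\epsilon_0\epsilon_w)}.  The result depends
#' only on \eqn{r/R}, \eqn{r_0/R}, \eqn{l_D/R} and
#' \eqn{\epsilon_l/\epsilon_w}; when the disk fills the cell
#' (\eqn{r_0 = R}) every higher mode vanishes and the value is exactly 1.
#'
#' @inheritParams sigma_profile
#' @param medium an [electrolyte_interface()].
#' @return numeric vector of \eqn{\Phi_s(r)/\Phi_0}.
#' @examples
#' g <- cell_geometry(R = 1, r0 = 1)
#' m <- electrolyte_interface(lD = 1, eps_ratio = 1)
#' surface_potential_cell(c(0, 0.5, 1), g, m)  # exactly 1, 1, 1
#' @export
surface_potential_cell <- function(r_over_R, geom, medium,
                                   ctrl = series_control()) {
  d <- .dims(geom, medium)
  stopifnot(inherits(ctrl, "series_control"))
  if (any(r_over_R < 0 | r_over_R > 1)) stop("'r_over_R' must lie in [0, 1]")
  weight_fun <- function(yn) {
    (2 / d$rho) * .bessel_j(yn * d$rho, 1) /
      (yn * .bessel_j(yn, 0)^2) / .mode_denominator(yn, d$lam, d$eta)
  }
  if (is.null(ctrl$n_max)) {
    .cell_series_adaptive(r_over_R, weight_fun, ctrl$rel_tol)$value
  } else {
    yn <- .zeros_j1(ctrl$n_max)
    .cell_series_sum(r_over_R, weight_fun(yn), yn)
  }
}

#' Scaled surface potential of a point charge inside the cell
#'
#' The \eqn{r_0 \to 0} limit of the disk series:
#' \deqn{\frac{\Phi_s(r)}{\Phi_0} = 1 + \sum_{n\ge1}
#'   \frac{J_0(y_n r/R)}{g(y_n)\,[J_0(y_n)]^2}.}
#' The sum converges only conditionally (terms decay like
#' \eqn{n^{-1/2}/g}), so an explicit `n_max` is required and the plain
#' partial sum can oscillate visibly when \eqn{l_D \ll R}.  With
#' `tail_average = TRUE` the returned value is the repeatedly averaged
#' (Euler-transformed) tail of the partial-sum sequence, which damps the
#' oscillation by many orders of magnitude for \eqn{r > 0}.  The potential
#' diverges at the charge itself, so \eqn{r = 0} is rejected.
#'
#' @param r_over_R radii (vectorized), each in (0, 1].
#' @param medium an [electrolyte_interface()]; the cell radius enters only
#'   through the ratio `lD_over_R`.
#' @param ctrl a [series_control()] with non-NULL `n_max`.
#' @param lD_over_R Debye length in units of the cell radius; defaults to
#'   `medium$lD`, i.e. the medium's length unit is taken to be R.
#' @param tail_average average the last `min(n_max/4, 200)` partial sums
#'   by repeated pairwise means instead of returning the raw partial sum.
#' @return numeric vector of \eqn{\Phi_s(r)/\Phi_0}.
#' @export
surface_potential_point_cell <- function(r_over_R, medium, ctrl,
                                         lD_over_R = medium$lD,
                                         tail_average = FALSE) {
  stopifnot(inherits(medium, "electrolyte_interface"),
            inherits(ctrl, "series_control"))
  if (is.null(ctrl$n_max)) {
    stop("the point-charge cell series needs an explicit 'n_max'")
  }
  if (any(r_over_R <= 0)) {
    stop("the point-charge potential diverges at r = 0; r_over_R must be > 0")
  }
  if (any(r_over_R > 1)) stop("'r_over_R' must lie in (0, 1]")
  yn <- .zeros_j1(ctrl$n_max)
  w <- 1 / (.bessel_j(yn, 0)^2 * .mode_denominator(yn, lD_over_R,
                                                   medium$eps_ratio))
  vapply(r_over_R, function(xi) {
    terms <- w * .bessel_j(yn * xi, 0)
    if (!tail_average) return(1 + .kahan_sum(terms))
    S <- 1 + cumsum(terms)
    k <- min(length(S) %/% 4L, 200L)
    Tm <- S[(length(S) - k + 1):length(S)]
    while (length(Tm) > 1) Tm <- (Tm[-1] + Tm[-length(Tm)]) / 2
    Tm
  }, 0)
}

#' Electrostatic potential above and below the interface
#'
#' The full axisymmetric mode expansions: for \eqn{z \ge 0} (electrolyte)
#' each mode decays as \eqn{\exp[-z\sqrt{(y_n/R)^2 + 1/l_D^2}]}; for
#' \eqn{z \le 0} (salt-free medium, Laplace equation) as
#' \eqn{\exp(y_n z/R)}.  Both branches share the same coefficients, so the
#' potential is continuous across \eqn{z = 0}.
#'
#' @inheritParams surface_potential_cell
#' @param z_over_R single height in units of R; its sign selects the
#'   branch (z = 0 gives the shared surface value).
#' @param derivative `"none"` for \eqn{\Phi/\Phi_0}, `"dz"` for
#'   \eqn{d(\Phi/\Phi_0)/d(z/R)} on the selected branch (at z = 0: the
#'   one-sided derivative of that branch).
#' @param branch `"auto"` picks the branch from the sign of `z_over_R`;
#'   `"electrolyte"` (z >= 0) or `"dielectric"` (z <= 0) select explicitly,
#'   which matters only for one-sided derivatives at z = 0.
#' @return numeric vector over `r_over_R`.
#' @export
potential_field <- function(r_over_R, z_over_R, geom, medium,
                            ctrl = series_control(n_max = 2000),
                            derivative = c("none", "dz"),
                            branch = c("auto", "electrolyte", "dielectric")) {
  derivative <- match.arg(derivative)
  branch <- match.arg(branch)
  d <- .dims(geom, medium)
  stopifnot(length(z_over_R) == 1, is.finite(z_over_R))
  if (branch == "auto") {
    branch <- if (z_over_R >= 0) "electrolyte" else "dielectric"
  }
  if ((branch == "electrolyte" && z_over_R < 0) ||
      (branch == "dielectric" && z_over_R > 0)) {
    stop("'z_over_R' lies outside the requested branch")
  }
  n_max <- if (is.null(ctrl$n_max)) 2000L else ctrl$n_max
  yn <- .zeros_j1(n_max)
  cn <- (2 / d$rho) * .bessel_j(yn * d$rho, 1) / (yn * .bessel_j(yn, 0)^2)
  an <- cn / .mode_denominator(yn, d$lam, d$eta)
  if (branch == "electrolyte") {
    kap <- sqrt(yn^2 + 1 / d$lam^2)
    zfac <- exp(-z_over_R * kap)
    a0 <- exp(-z_over_R / d$lam)
    if (derivative == "dz") {
      zfac <- -kap * zfac
      a0 <- -a0 / d$lam
    }
  } else {
    zfac <- exp(yn * z_over_R)
    a0 <- 1
    if (derivative == "dz") {
      zfac <- yn * zfac
      a0 <- 0
    }
  }
  vapply(r_over_R, function(xi) {
    a0 + sum(an * zfac * .bessel_j(yn * xi, 0))
  }, 0)
}
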