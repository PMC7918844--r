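## Isolated-disk and point-charge surface potentials by zeroth-order
## Hankel transform.  The semi-infinite integrands oscillate through a
## Bessel factor and decay slowly, so the integral is partitioned at the
## zeros of the dominant oscillatory factor and the alternating sequence
## of partial sums is accelerated by repeated pairwise averaging (an
## Euler-type transformation).  A plain upper cutoff would bias the
## dipole tail that dominates the far field at small eps_l/eps_w.

.osc_integrate <- function(f, breaks, rel_tol = 1e-10) {
  panels <- vapply(seq_len(length(breaks) - 1L), function(k) {
    out <- tryCatch(
      stats::integrate(f, breaks[k], breaks[k + 1], rel.tol = rel_tol,
                       abs.tol = 0, subdivisions = 200L),
      error = function(e) e)
    if (inherits(out, "error")) {
      stop(sprintf(
        "panel quadrature failed on [%g, %g] (%d panels): %s",
        breaks[k], breaks[k + 1], length(breaks) - 1L,
        conditionMessage(out)))
    }
    out$value
  }, 0)
  S <- cumsum(panels)
  k <- min(length(S), 60L)
  Tm <- S[(length(S) - k + 1):length(S)]
  prev <- Tm[length(Tm)]
  while (length(Tm) > 1) {
    prev <- Tm[length(Tm)]
    Tm <- (Tm[-1] + Tm[-length(Tm)]) / 2
  }
  list(value = Tm, residual = abs(Tm - prev), n_panels = length(panels))
}

#' Scaled surface potential of a single isolated charged disk
#'
#' The infinite-cell (R -> infinity) reference state: a lone disk of radius
#' \eqn{r_0} and density \eqn{\bar\sigma = \sigma_0 R^2/r_0^2} at the
#' interface,
#' \deqn{\frac{\Phi_s^{self}(r)}{\Phi_0} = \frac{R}{r_0} \int_0^\infty
#'   \mathrm{d}y\, \frac{J_0(y r/R)\, J_1(y r_0/R)}{g(y)}.}
#' The reference radius R enters only through the normalisations
#' \eqn{\Phi_0} and \eqn{\bar\sigma}; in unscaled variables the result is
#' independent of R.
#'
#' @param r radius (vectorized), same length unit as `geom`; `r >= 0`.
#' @param geom a [cell_geometry()] (its `R` is the normalisation radius).
#' @param medium an [electrolyte_interface()].
#' @param n_panels number of oscillation panels before acceleration.
#' @param rel_tol per-panel quadrature tolerance.
#' @return numeric vector of \eqn{\Phi_s^{self}(r)/\Phi_0}.
#' @export
surface_potential_isolated <- function(r, geom, medium, n_panels = 240L,
                                       rel_tol = 1e-10) {
  d <- .dims(geom, medium)
  if (any(r < 0)) stop("'r' must be >= 0")
  x_all <- r / geom$R
  g <- function(y) .mode_denominator(y, d$lam, d$eta)
  vapply(x_all, function(x) {
    f <- function(y) .bessel_j(y * x, 0) * .bessel_j(y * d$rho, 1) / g(y)
    breaks <- if (x >= d$rho) {
      c(0, .zeros_j0(n_panels) / x)
    } else {
      c(0, .zeros_j1(n_panels) / d$rho)
    }
    .osc_integrate(f, breaks, rel_tol)$value / d$rho
  }, 0)
}

#' Stillinger point-charge surface potential at the interface
#'
#' The \eqn{r_0 \to 0} limit of the isolated disk,
#' \deqn{\frac{\Phi_s^{self}(r)}{\Phi_0} = \frac{1}{2} \int_0^\infty
#'   \mathrm{d}y\, \frac{y\, J_0(y r/R)}{g(y)},}
#' evaluated after substituting \eqn{t = y\,r/R} so that the Bessel factor
#' oscillates with unit period and the prefactor \eqn{(R/r)^2/2} is pulled
#' out.  The integral converges only conditionally and the potential
#' diverges as \eqn{r \to 0}, so `r = 0` is rejected.
#'
#' @param r radius (vectorized), `r > 0`, same unit as `R_scale` and the
#'   Debye length.
#' @param medium an [electrolyte_interface()].
#' @param R_scale normalisation radius entering \eqn{\Phi_0} and
#'   \eqn{\bar\sigma} (the potential scales as `R_scale^2`).
#' @inheritParams surface_potential_isolated
#' @return numeric vector of \eqn{\Phi_s^{self}(r)/\Phi_0}.
#' @export
surface_potential_point_isolated <- function(r, medium, R_scale = 1,
                                             n_panels = 200L,
                                             rel_tol = 1e-10) {
  stopifnot(inherits(medium, "electrolyte_interface"), R_scale > 0)
  if (any(r <= 0)) {
    stop("the point-charge potential diverges at r = 0; 'r' must be > 0")
  }
  vapply(r, function(ri) {
    q <- medium$lD / ri
    f <- function(t) {
      t * .bessel_j(t, 0) / .mode_denominator(t, q, medium$eps_ratio)
    }
    breaks <- c(0, .zeros_j0(n_panels))
    0.5 * (R_scale / ri)^2 * .osc_integrate(f, breaks, rel_tol)$value
  }, 0)
}

#' Screened-Coulomb plus dipole far-field asymptote
#'
#' Closed-form approximation to the point-charge surface potential, valid
#' for \eqn{\epsilon_l \ll \epsilon_w} and \eqn{l_D \ll r}:
#' \deqn{\frac{\Phi_s^{self}(r)}{\Phi_0} = \frac{1}{2}\frac{R^2}{l_D^2}
#'   \left[\frac{l_D}{r} e^{-r/l_D} +
#'   \frac{\epsilon_l}{\epsilon_w}\frac{l_D^3}{r^3}\right].}
#' The \eqn{r^{-3}} term is the field of the dipole formed by the surface
#' charge and its counterion cloud, transmitted through the low-dielectric
#' medium.
#'
#' @inheritParams surface_potential_point_isolated
#' @return numeric vector of the asymptotic \eqn{\Phi_s^{self}(r)/\Phi_0}.
#' @examples
#' m <- electrolyte_interface(lD = 1, eps_ratio = 1)
#' hurd_asymptotic(1, m)  # (exp(-1) + 1)/2
#' @export
hurd_asymptotic <- function(r, medium, R_scale = 1) {
  stopifnot(inherits(medium, "electrolyte_interface"), R_scale > 0)
  if (any(r <= 0)) stop("'r' must be > 0")
  lD <- medium$lD
  0.5 * (R_scale / lD)^2 *
    ((lD / r) * exp(-r / lD) + medium$eps_ratio * (lD / r)^3)
}

#' Difference potential: field of all other cells
#'
#' \eqn{\Delta\Phi_s(r) = \Phi_s(r) - \Phi_s^{self}(r)}: the in-cell
#' surface potential minus the isolated-disk self-potential, i.e. the
#' potential produced at the central cell by every other charged disk.
#' This is the quantity that enters the interaction free energy.  Both
#' constituents are evaluated for the identical (finite-r0) geometry; the
#' point-charge case is approached through small `r0`, where the
#' divergences of the two terms cancel.
#'
#' @param r_over_R strictly increasing grid in [0, 1].
#' @inheritParams surface_potential_cell
#' @return a [radial_profile()] of kind `"potential_difference"`.
#' @export
delta_surface_potential <- function(r_over_R = seq(0, 1, length.out = 201),
                                    geom, medium, ctrl = series_control()) {
  cellv <- surface_potential_cell(r_over_R, geom, medium, ctrl)
  selfv <- surface_potential_isolated(r_over_R * geom$R, geom, medium)
  radial_profile(r_over_R, cellv - selfv, "potential_difference",
                 params = list(R = geom$R, r0 = geom$r0, lD = medium$lD,
                               eps_ratio = medium$eps_ratio))
}
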