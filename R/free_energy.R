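## Discrete-to-continuum free-energy ratio F/F0.
##
## F/A multiplies the step charge density in a cell by the potential of all
## other cells, which after integrating over the Bessel modes gives
##   F/F0 = 1 + (R/r0)^2 [ sum_{n=1..nmax} S_n - int_0^{y_nmax} I(y) dy ],
##   S_n  = [2 J1(y_n r0/R) / (y_n J0(y_n))]^2 / g(y_n),
##   I(y) = (2/y) J1(y r0/R)^2 / g(y).
## Sum and integral diverge separately as the cutoff grows; only the
## shared-cutoff (paired) combination is finite.  The integral is split at
## the same Bessel zeros y_n that index the sum, each panel handled by
## fixed 16-point Gauss-Legendre quadrature, and the pairing S_n - I_n is
## accumulated term by term so the cancellation happens at full precision.

.gauss16 <- function() {
  gl <- get0("gl16", envir = .dh_cache)
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(16, -1, 1)
    assign("gl16", gl, envir = .dh_cache)
  }
  gl
}

## paired per-mode contributions (S_n - I_n)/rho^2, n = 1..n_max
.fe_terms <- function(rho, lam, eta, n_max) {
  gl <- .gauss16()
  yn <- .zeros_j1(n_max)
  yz <- c(0, yn)
  Sn <- (2 * .bessel_j(yn * rho, 1) / (yn * .bessel_j(yn, 0)))^2 /
    .mode_denominator(yn, lam, eta)
  mid <- (yz[-1] + yz[-(n_max + 1)]) / 2
  hw <- (yz[-1] - yz[-(n_max + 1)]) / 2
  Y <- outer(hw, gl$x) + mid
  Fv <- (2 / Y) * .bessel_j(as.vector(Y * rho), 1)^2 /
    .mode_denominator(Y, lam, eta)
  dim(Fv) <- dim(Y)
  In <- hw * as.vector(Fv %*% gl$w)
  (Sn - In) / rho^2
}

.fe_result <- function(ratio, n_max, r0, conv, geom, medium,
                       interaction_only = TRUE, iterates = NULL) {
  structure(list(ratio = ratio, n_max_used = as.integer(n_max),
                 r0_used = r0, convergence_estimate = conv,
                 interaction_only = interaction_only,
                 geom = geom, medium = medium, iterates = iterates),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("F/F0 = %.8g  (n_max = %d, r0 = %g, convergence ~ %.2g)\n",
              x$ratio, x$n_max_used, x$r0_used, x$convergence_estimate))
  invisible(x)
}

#' Free-energy ratio F/F0 for charged disks in Wigner-Seitz cells
#'
#' Ratio of the Debye-Huckel interaction free energy of the discrete-disk
#' ensemble to the continuum (uniformly smeared) free energy
#' \eqn{F_0/A = \sigma_0^2 l_D/(2\epsilon_w\epsilon_0)}.  The mode sum and
#' the Hankel (self-energy) integral are truncated at the *same* cutoff
#' \eqn{y_{n_{max}}} -- each piece diverges on its own -- and combined
#' mode by mode.
#'
#' With `ctrl$n_max = NULL` the truncation is doubled, starting from
#' \eqn{5R/r_0}, until the ratio changes by less than `ctrl$rel_tol`
#' (relative, with an absolute floor of `rel_tol/100` so that ratios near
#' zero can converge).  A fixed `ctrl$n_max` reproduces a prescribed
#' truncation, e.g. for convergence studies; the `convergence_estimate`
#' field then reports the relative contribution of the last half of the
#' modes, a proxy for the truncation error.
#'
#' @param geom a [cell_geometry()].
#' @param medium an [electrolyte_interface()].
#' @param ctrl a [series_control()].
#' @param interaction_only if `FALSE`, the self-energy integral is *not*
#'   subtracted (the potential of all disks, not just the other cells,
#'   multiplies the charge).  With `r0 = R` this reproduces the continuum
#'   value 1 exactly.
#' @return a `free_energy_result` with fields `ratio`, `n_max_used`,
#'   `r0_used`, `convergence_estimate`.
#' @examples
#' g <- cell_geometry(R = 1, r0 = 0.3)
#' m <- electrolyte_interface(lD = 1, eps_ratio = 1)
#' free_energy_ratio(g, m)
#' @export
free_energy_ratio <- function(geom, medium, ctrl = series_control(),
                              interaction_only = TRUE) {
  d <- .dims(geom, medium)
  stopifnot(inherits(ctrl, "series_control"))
  sum_terms <- function(n_max) {
    if (!interaction_only) {
      yn <- .zeros_j1(n_max)
      Sn <- (2 * .bessel_j(yn * d$rho, 1) / (yn * .bessel_j(yn, 0)))^2 /
        .mode_denominator(yn, d$lam, d$eta)
      return(1 + .kahan_sum(Sn) / d$rho^2)
    }
    1 + .kahan_sum(.fe_terms(d$rho, d$lam, d$eta, n_max))
  }
  if (!is.null(ctrl$n_max)) {
    n_max <- ctrl$n_max
    ratio <- sum_terms(n_max)
    half <- sum_terms(max(1L, n_max %/% 2L))
    conv <- abs(ratio - half) / max(abs(ratio), 1e-2)
    return(.fe_result(ratio, n_max, geom$r0, conv, geom, medium,
                      interaction_only))
  }
  n_max <- max(64L, ceiling(5 / d$rho))
  prev <- NA_real_
  repeat {
    ratio <- sum_terms(n_max)
    if (!is.na(prev)) {
      conv <- abs(ratio - prev) / max(abs(ratio), 1e-2)
      if (abs(ratio - prev) < max(ctrl$rel_tol * abs(ratio),
                                  ctrl$rel_tol * 1e-2)) {
        return(.fe_result(ratio, n_max, geom$r0, conv, geom, medium,
                          interaction_only))
      }
    }
    prev <- ratio
    n_max <- 2L * n_max
    if (n_max > 2^22) {
      warning("free-energy truncation cap reached before requested tolerance")
      return(.fe_result(ratio, n_max %/% 2L, geom$r0, NA_real_, geom, medium,
                        interaction_only))
    }
  }
}

#' Point-charge limit of the free-energy ratio
#'
#' The limit \eqn{r_0 \to 0} cannot be taken in closed form (the formal
#' limiting expression contains two separately diverging contributions),
#' but because \eqn{d(F/F_0)/dr_0 = 0} at \eqn{r_0 = 0}, evaluating at a
#' small finite disk is second-order accurate.  The procedure starts at
#' \eqn{r_0 = 0.05\,\min(R, l_D)}; at each \eqn{r_0} the truncation is
#' grown from \eqn{5R/r_0} by doubling until the ratio is converged (the
#' truncated expression approaches its limit only for
#' \eqn{n_{max} \gg R/r_0}), and \eqn{r_0} is then halved until successive
#' ratios agree to `rel_tol` (relative, absolute floor `rel_tol/100`).
#'
#' @param R cell radius (same unit as `medium$lD`).
#' @param medium an [electrolyte_interface()].
#' @param rel_tol convergence tolerance for the \eqn{r_0} iteration.
#' @param max_halve maximum number of \eqn{r_0} halvings before giving up.
#' @param r0_factor starting disk radius as a fraction of
#'   \eqn{\min(R, l_D)}.
#' @return a `free_energy_result`; `iterates` holds the sequence of ratios
#'   over the \eqn{r_0} halvings.
#' @examples
#' m <- electrolyte_interface(lD = 1, eps_ratio = 1)
#' point_charge_free_energy(R = 1, m, rel_tol = 1e-3)
#' @export
point_charge_free_energy <- function(R = 1, medium, rel_tol = 1e-4,
                                     max_halve = 6L, r0_factor = 0.05) {
  stopifnot(inherits(medium, "electrolyte_interface"), R > 0,
            rel_tol > 0, r0_factor > 0)
  lam <- medium$lD / R
  eta <- medium$eps_ratio
  rho <- r0_factor * min(1, lam)
  converge_nmax <- function(rho, m_start) {
    m <- m_start
    prev <- NA_real_
    repeat {
      v <- 1 + .kahan_sum(.fe_terms(rho, lam, eta, ceiling(m / rho)))
      if (!is.na(prev) &&
            abs(v - prev) < max(rel_tol * abs(v) / 2, rel_tol * 5e-3)) {
        return(list(value = v, m = m))
      }
      prev <- v
      m <- 2 * m
      if (m > 2560) {
        warning("inner truncation cap reached in point-charge limit")
        return(list(value = v, m = m))
      }
    }
  }
  iterates <- numeric(0)
  m_start <- 5
  prev <- NA_real_
  for (k in 0:max_halve) {
    inner <- converge_nmax(rho, m_start)
    m_start <- max(5, inner$m / 2)  # warm start: bias is stable under halving
    iterates <- c(iterates, inner$value)
    if (!is.na(prev)) {
      delta <- abs(inner$value - prev)
      if (delta < max(rel_tol * abs(inner$value), rel_tol * 1e-2)) {
        return(.fe_result(inner$value, ceiling(inner$m / rho), rho * R,
                          delta / max(abs(inner$value), 1e-2),
                          cell_geometry(R, rho * R), medium,
                          iterates = iterates))
      }
    }
    prev <- inner$value
    rho <- rho / 2
  }
  stop(sprintf(
    "point-charge limit did not converge after %d halvings; iterates: %s",
    max_halve, paste(signif(iterates, 6), collapse = ", ")))
}

#' Scaled free-energy sweep over surface charge density
#'
#' For point charges of average density \eqn{\sigma_0}, the cell radius is
#' tied to the charge density by \eqn{\sigma_0 \pi R^2 = e}.  In the
#' scaled variables \eqn{s = l_D^2 \sigma_0 / e} (scaled charge density)
#' and \eqn{f_s = 2 l_D^3 \epsilon_w \epsilon_0 F/(e^2 A)} (scaled free
#' energy) this means \eqn{R/l_D = (\pi s)^{-1/2}} and
#' \eqn{f_s = (F/F_0)\, s^2}; the continuum model gives \eqn{f_s = s^2}
#' exactly.  At small \eqn{s} and nonzero \eqn{\epsilon_l/\epsilon_w} the
#' dipolar interactions flatten the curve to \eqn{f_s \sim s^{2.5}}.
#'
#' @param s_values positive scaled charge densities.
#' @param eps_ratio dielectric ratio \eqn{\epsilon_l/\epsilon_w}.
#' @param rel_tol tolerance for the point-charge limit at each `s`.
#' @return a data frame of class `scaled_sweep` with columns `s`, `fs`,
#'   `fs_continuum`, `F_over_F0`, `eps_ratio`, `lD_over_R`, `n_max_used`,
#'   `r0_used`, `convergence_estimate`.
#' @export
scaled_sweep <- function(s_values, eps_ratio, rel_tol = 1e-4) {
  if (any(s_values <= 0)) stop("all 's_values' must be > 0")
  medium <- electrolyte_interface(lD = 1, eps_ratio = eps_ratio)
  rows <- lapply(s_values, function(s) {
    R <- (pi * s)^(-1 / 2)   # in units of lD
    fe <- point_charge_free_energy(R, medium, rel_tol = rel_tol)
    data.frame(s = s, fs = fe$ratio * s^2, fs_continuum = s^2,
               F_over_F0 = fe$ratio, eps_ratio = eps_ratio,
               lD_over_R = 1 / R, n_max_used = fe$n_max_used,
               r0_used = fe$r0_used,
               convergence_estimate = fe$convergence_estimate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scaled_sweep", "data.frame")
  out
}

#' Log-log slope of a scaled free-energy sweep
#'
#' Least-squares slope of \eqn{\log f_s} against \eqn{\log s}; with two
#' points this is the exact two-point slope.  The continuum law gives 2,
#' the dipole-dominated regime 2.5.
#'
#' @param s either a `scaled_sweep` data frame (columns `s`, `fs`) or a
#'   numeric vector of scaled charge densities.
#' @param fs scaled free energies when `s` is a vector.
#' @return the slope (dimensionless scalar).
#' @examples
#' loglog_slope(c(1e-3, 1e-2, 1e-1), c(1e-3, 1e-2, 1e-1)^2.5)  # 2.5
#' @export
loglog_slope <- function(s, fs = NULL) {
  if (is.data.frame(s)) {
    fs <- s$fs
    s <- s$s
  }
  if (length(s) < 2 || length(fs) != length(s)) {
    stop("need at least two (s, fs) pairs")
  }
  if (any(s <= 0) || any(fs <= 0)) stop("'s' and 'fs' must be positive")
  if (anyDuplicated(s)) stop("'s' values must be distinct")
  unname(coef(lm(log(fs) ~ log(s)))[2])
}

#' Convert a free-energy ratio to physical units
#'
#' Applies the continuum scale \eqn{F_0/A = \sigma_0^2 l_D /
#' (2\epsilon_w\epsilon_0)} with \eqn{\sigma_0 = e/(\pi R^2)} (one
#' elementary charge per cell; the sign of \eqn{\sigma_0} is irrelevant --
#' everything is quadratic in it).  Lengths in `result$geom` and
#' `medium$lD` are interpreted in metres.
#'
#' @param result a `free_energy_result`.
#' @param medium an [electrolyte_interface()] carrying the physical block.
#' @return a list of class `dh_physical`: `F_per_area` (J/m^2),
#'   `F_per_charge_kBT` (per-charge free energy in units of
#'   \eqn{k_B T}), `sigma0` (C/m^2), `Phi0` (V), plus the inputs.
#' @export
to_physical_units <- function(result, medium) {
  stopifnot(inherits(result, "free_energy_result"),
            inherits(medium, "electrolyte_interface"))
  if (is.null(medium$physical)) {
    stop("'medium' must carry the physical block (eps_w, temperature, n0)")
  }
  cst <- .dh_constants
  R <- result$geom$R
  lD <- medium$lD
  eps_w <- medium$physical$eps_w
  sigma0 <- cst$e / (pi * R^2)
  F0_per_area <- sigma0^2 * lD / (2 * eps_w * cst$eps0)
  F_per_area <- result$ratio * F0_per_area
  structure(list(
    F_per_area = F_per_area,
    F_per_charge_kBT = F_per_area * pi * R^2 /
      (cst$kB * medium$physical$temperature),
    sigma0 = sigma0,
    Phi0 = sigma0 * lD / (cst$eps0 * eps_w),
    ratio = result$ratio, R = R, lD = lD
  ), class = "dh_physical")
}

#' @export
print.dh_physical <- function(x, ...) {
  cat(sprintf("F/A = %.6g J/m^2  (F per charge = %.6g kBT; F/F0 = %.6g)\n",
              x$F_per_area, x$F_per_charge_kBT, x$ratio))
  invisible(x)
}
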