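## Parameter containers.  All downstream computations are dimensionless in
## (r/R, r0/R, lD/R, eps_l/eps_w); these objects carry the lengths in
## whatever consistent unit the caller chose.

#' Wigner-Seitz cell geometry
#'
#' @param R cell radius (any length unit, > 0).
#' @param r0 charged-disk radius, 0 < `r0` <= `R`.
#' @return object of class `cell_geometry` with fields `R`, `r0` and the
#'   derived ratio `r0_over_R`.
#' @examples
#' cell_geometry(R = 1, r0 = 0.4)
#' @export
cell_geometry <- function(R = 1, r0) {
  if (!(length(R) == 1 && is.numeric(R) && R > 0)) stop("'R' must be > 0")
  if (!(length(r0) == 1 && is.numeric(r0) && r0 > 0 && r0 <= R)) {
    stop("'r0' must satisfy 0 < r0 <= R")
  }
  structure(list(R = R, r0 = r0, r0_over_R = r0 / R),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Wigner-Seitz cell: R = %g, r0 = %g (r0/R = %g)\n",
              x$R, x$r0, x$r0_over_R))
  invisible(x)
}

#' Electrolyte / low-dielectric interface description
#'
#' Holds the Debye length of the salt solution and the dielectric ratio
#' \eqn{\epsilon_l/\epsilon_w} of the salt-free medium to the electrolyte.
#' An optional physical block (`eps_w`, `temperature`, `n0`) enables unit
#' conversion; when both `lD` and the block are supplied they must agree
#' through the Debye-length formula to 1e-6 relative.
#'
#' @param lD Debye length (same length unit as the geometry).  May be
#'   omitted when the physical block is given, in which case it is computed
#'   (in metres).
#' @param eps_ratio dielectric ratio \eqn{\epsilon_l/\epsilon_w \ge 0};
#'   0 means a perfectly non-polarizable lower medium.
#' @param eps_w,temperature,n0 optional physical block: relative dielectric
#'   constant of the electrolyte, temperature (K) and bulk 1:1 salt number
#'   density (m^-3).
#' @return object of class `electrolyte_interface`.
#' @examples
#' electrolyte_interface(lD = 1, eps_ratio = 1)
#' electrolyte_interface(eps_ratio = 0.025, eps_w = 80, temperature = 298,
#'                       n0 = 9.3e25)
#' @export
electrolyte_interface <- function(lD = NULL, eps_ratio,
                                  eps_w = NULL, temperature = NULL,
                                  n0 = NULL) {
  if (!(length(eps_ratio) == 1 && is.numeric(eps_ratio) && eps_ratio >= 0)) {
    stop("'eps_ratio' must be a single value >= 0")
  }
  physical <- NULL
  if (!is.null(eps_w) || !is.null(temperature) || !is.null(n0)) {
    if (is.null(eps_w) || is.null(temperature) || is.null(n0)) {
      stop("the physical block needs all of 'eps_w', 'temperature', 'n0'")
    }
    physical <- list(eps_w = eps_w, temperature = temperature, n0 = n0)
    lD_phys <- debye_length(eps_w, temperature, n0)
    if (is.null(lD)) {
      lD <- lD_phys
    } else if (abs(lD - lD_phys) > 1e-6 * lD_phys) {
      stop(sprintf(
        "'lD' (%g) is inconsistent with the physical block (Debye length %g)",
        lD, lD_phys))
    }
  }
  if (!(length(lD) == 1 && is.numeric(lD) && lD > 0)) {
    stop("'lD' must be a single positive length")
  }
  structure(list(lD = lD, eps_ratio = eps_ratio, physical = physical),
            class = "electrolyte_interface")
}

#' @export
print.electrolyte_interface <- function(x, ...) {
  cat(sprintf("Electrolyte interface: lD = %g, eps_l/eps_w = %g\n",
              x$lD, x$eps_ratio))
  if (!is.null(x$physical)) {
    cat(sprintf("  physical block: eps_w = %g, T = %g K, n0 = %g m^-3\n",
                x$physical$eps_w, x$physical$temperature, x$physical$n0))
  }
  invisible(x)
}

#' Series truncation and convergence control
#'
#' @param n_max truncation order of Fourier-Bessel sums, or `NULL` for
#'   adaptive selection (doubling until the partial result changes by less
#'   than `rel_tol`).  The point-charge cell series converges only
#'   conditionally and requires an explicit `n_max`.
#' @param rel_tol relative convergence tolerance used by adaptive
#'   truncation and by the point-charge free-energy iteration.
#' @return object of class `series_control`.
#' @export
series_control <- function(n_max = NULL, rel_tol = 1e-6) {
  if (!is.null(n_max)) {
    if (!(length(n_max) == 1 && is.numeric(n_max) && n_max >= 1 &&
            n_max == floor(n_max))) {
      stop("'n_max' must be NULL or a single integer >= 1")
    }
    n_max <- as.integer(n_max)
  }
  if (!(length(rel_tol) == 1 && is.numeric(rel_tol) && rel_tol > 0)) {
    stop("'rel_tol' must be > 0")
  }
  structure(list(n_max = n_max, rel_tol = rel_tol), class = "series_control")
}

#' Radial profile container
#'
#' A data frame of scaled values on a radial grid, tagged with the quantity
#' it holds (`"charge"` for \eqn{\sigma/\sigma_0}, `"potential"` for
#' \eqn{\Phi_s/\Phi_0}, `"potential_difference"` for
#' \eqn{\Delta\Phi_s/\Phi_0}) and the parameter set that produced it.
#'
#' @param r_over_R strictly increasing radii in [0, 1] (or r/lD for
#'   isolated-geometry profiles; see `params`).
#' @param value scaled values on that grid.
#' @param kind one of `"charge"`, `"potential"`, `"potential_difference"`.
#' @param params named list of parameters recorded as metadata.
#' @return a data frame of class `radial_profile` with attributes `kind`
#'   and `params`.
#' @export
radial_profile <- function(r_over_R, value, kind, params = list()) {
  kind <- match.arg(kind, c("charge", "potential", "potential_difference"))
  if (length(r_over_R) != length(value)) stop("grid/value length mismatch")
  if (any(diff(r_over_R) <= 0)) stop("'r_over_R' must be strictly increasing")
  out <- data.frame(r_over_R = r_over_R, value = value)
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile (%s), %d points on [%g, %g]\n",
              attr(x, "kind"), nrow(x), min(x$r_over_R), max(x$r_over_R)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

## dimensionless view of a (geometry, medium) pair
.dims <- function(geom, medium) {
  stopifnot(inherits(geom, "cell_geometry"),
            inherits(medium, "electrolyte_interface"))
  list(rho = geom$r0 / geom$R, lam = medium$lD / geom$R,
       eta = medium$eps_ratio)
}

## compensated (Kahan) summation in fixed order, for scalar series tails
.kahan_sum <- function(x) {
  s <- 0
  c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}
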