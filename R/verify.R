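## Cross-validation suite: every semi-analytic path in the package is
## checked against an independent route (finite differences, direct
## quadrature of the defining integral, closed-form asymptote, or an
## exact identity).

## Direct radial quadrature of the interaction free energy:
##   F/F0 = (2/rho^2) int_0^rho x [Phi_cell(x) - Phi_self(x)] dx
## evaluated with 32-point Gauss-Legendre on [0, rho].  This is the
## independent oracle for the paired mode-sum expression.
.free_energy_by_quadrature <- function(geom, medium,
                                       ctrl = series_control(n_max = 50000)) {
  d <- .dims(geom, medium)
  gl <- pracma::gaussLegendre(32, 0, d$rho)
  cellv <- surface_potential_cell(gl$x, geom, medium, ctrl)
  selfv <- surface_potential_isolated(gl$x * geom$R, geom, medium)
  (2 / d$rho^2) * sum(gl$w * gl$x * (cellv - selfv))
}

#' Run the internal cross-validation suite
#'
#' Each check pits one computational route against an independent one:
#' \enumerate{
#'   \item uniform-charge identity: \eqn{r_0 = R} forces
#'     \eqn{\Phi_s/\Phi_0 \equiv 1} at coefficient level;
#'   \item Fourier-Bessel series vs the finite-difference solution;
#'   \item paired mode-sum free energy vs direct radial quadrature of
#'     \eqn{\sigma \Delta\Phi_s};
#'   \item isolated-disk Hankel potential vs the large-cell extrapolation
#'     of the series (Aitken over \eqn{R/l_D = 4, 8, 16});
#'   \item Stillinger point-charge integral vs the screened-Coulomb +
#'     dipole asymptote at \eqn{r = 20 l_D};
#'   \item dipole-tail log-log slope \eqn{-3};
#'   \item point-charge flatness: two-point slope of \eqn{F/F_0} in
#'     \eqn{r_0/R} near zero.
#' }
#'
#' @param tight halve all thresholds (stricter pass criteria).
#' @param quiet suppress the printed report.
#' @return data frame with columns `check`, `value`, `threshold`, `pass`;
#'   attribute `ok` is `TRUE` when all rows pass.
#' @export
run_verification <- function(tight = FALSE, quiet = FALSE) {
  f <- if (tight) 0.5 else 1
  rows <- list()
  note <- function(check, value, threshold) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, threshold = threshold,
      pass = is.finite(value) && abs(value) < threshold)
  }

  m11 <- electrolyte_interface(lD = 1, eps_ratio = 1)

  ## 1: uniform-charge identity (exact)
  gu <- cell_geometry(R = 1, r0 = 1)
  vals <- surface_potential_cell(seq(0, 1, 0.1), gu,
                                 electrolyte_interface(lD = 0.3,
                                                       eps_ratio = 1.7),
                                 series_control(n_max = 500))
  note("uniform-identity", max(abs(vals - 1)), 1e-12)

  ## 2: series vs finite differences (lD = R, eps_l = eps_w, r0 = 0.4R)
  g4 <- cell_geometry(R = 1, r0 = 0.4)
  sol <- solve_cell_fd(g4, m11, grid_spec(nr = 128))
  ser <- surface_potential_cell(sol$r, g4, m11, series_control(n_max = 4000))
  note("series-vs-fd", max(abs(sol$profile$value - ser) / abs(ser)),
       0.01 * f)

  ## 3: paired mode sum vs direct quadrature of the free energy
  g02 <- cell_geometry(R = 1, r0 = 0.02)
  fe <- free_energy_ratio(g02, m11, series_control(n_max = 1000))
  oracle <- .free_energy_by_quadrature(g02, m11)
  note("energy-vs-quadrature", (fe$ratio - oracle) / oracle, 0.005 * f)

  ## 4: Hankel disk vs large-cell series extrapolation (disk-density scale)
  iso <- surface_potential_isolated(0, cell_geometry(R = 1, r0 = 1), m11)
  cells <- vapply(c(4, 8, 16), function(RL) {
    surface_potential_cell(0, cell_geometry(R = RL, r0 = 1),
                           m11, series_control(n_max = 30000)) / RL^2
  }, 0)
  ait <- cells[3] - (cells[3] - cells[2])^2 /
    ((cells[3] - cells[2]) - (cells[2] - cells[1]))
  note("hankel-vs-series", (ait - iso) / iso, 0.005 * f)

  ## 5: Stillinger integral vs far-field asymptote
  m001 <- electrolyte_interface(lD = 1, eps_ratio = 0.01)
  still <- surface_potential_point_isolated(20, m001)
  note("stillinger-vs-asymptote", (still - hurd_asymptotic(20, m001)) /
         hurd_asymptotic(20, m001), 0.05 * f)

  ## 6: dipole-tail slope -3 (eps_ratio = 0.1, r in [10, 40] lD)
  m01 <- electrolyte_interface(lD = 1, eps_ratio = 0.1)
  rs <- exp(seq(log(10), log(40), length.out = 5))
  sl <- loglog_slope(rs, surface_potential_point_isolated(rs, m01))
  note("dipole-tail-slope", sl + 3, 0.1 * f)

  ## 7: point-charge flatness of F/F0 in r0
  f1 <- free_energy_ratio(cell_geometry(R = 1, r0 = 0.01), m11,
                          series_control(n_max = 1000))$ratio
  f2 <- free_energy_ratio(cell_geometry(R = 1, r0 = 0.02), m11,
                          series_control(n_max = 1000))$ratio
  note("point-flatness", (f2 - f1) / 0.01, 0.05 * f)

  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  if (!quiet) {
    cat(sprintf("%-24s %14s %12s  %s\n", "check", "value", "threshold",
                "pass"))
    for (i in seq_len(nrow(out))) {
      cat(sprintf("%-24s %14.4g %12.4g  %s\n", out$check[i], out$value[i],
                  out$threshold[i], if (out$pass[i]) "ok" else "FAIL"))
    }
  }
  invisible(out)
}
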