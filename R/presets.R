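## Named parameter scans and the run functions behind the command-line
## interface.  Each preset reproduces one of the canonical parameter
## studies of the model: how profiles sharpen as the disk shrinks, how the
## cell potential approaches the isolated disk as the cell grows, how the
## truncated free energy converges, and the screening/charge-density maps
## of F/F0 and fs(s).

#' Predefined parameter scans
#'
#' \describe{
#'   \item{`"disk-size"`}{charge and potential profiles at
#'     \eqn{l_D = R}, \eqn{\epsilon_l = \epsilon_w} for
#'     \eqn{r_0/R \in \{0.4, 0.2, 0.1, 0.05, 0.025\}}.}
#'   \item{`"cell-size"`}{cell, isolated and difference potentials for a
#'     disk with \eqn{r_0 = l_D} in cells of
#'     \eqn{R/l_D \in \{1, 1.2, 1.5, 2, 4, \infty\}}, all scaled to the
#'     disk's own charge density.}
#'   \item{`"truncation"`}{\eqn{F/F_0} against \eqn{r_0/R} at
#'     \eqn{l_D = R}, \eqn{\epsilon_l = \epsilon_w} for truncations
#'     \eqn{n_{max} \in \{10, 33, 100, 333, 1000\}}.}
#'   \item{`"screening"`}{point-charge \eqn{F/F_0} over a log-spaced
#'     \eqn{l_D/R} grid for
#'     \eqn{\epsilon_l/\epsilon_w \in \{0, 0.1, 0.5, 1, 2\}}.}
#'   \item{`"charge-sweep"`}{scaled free energy \eqn{f_s(s)} over
#'     log-spaced \eqn{s} for
#'     \eqn{\epsilon_l/\epsilon_w \in \{0, 0.01, 0.1, 1\}}, with the
#'     continuum reference \eqn{s^2}.}
#' }
#'
#' @param name one of the preset names above.
#' @return a list with elements `kind` and `params` (a data frame), ready
#'   for [run_potential_profiles()] or [run_free_energy()].
#' @export
preset_parameters <- function(name = c("disk-size", "cell-size",
                                       "truncation", "screening",
                                       "charge-sweep")) {
  name <- match.arg(name)
  switch(name,
    "disk-size" = list(
      kind = "potential", preset = name,
      params = data.frame(r0_over_R = c(0.4, 0.2, 0.1, 0.05, 0.025),
                          lD_over_R = 1, eps_ratio = 1)),
    "cell-size" = list(
      kind = "potential-isolated", preset = name,
      params = data.frame(R_over_lD = c(1, 1.2, 1.5, 2, 4, Inf),
                          r0_over_lD = 1, eps_ratio = 1)),
    "truncation" = list(
      kind = "free-energy", preset = name,
      params = expand.grid(
        r0_over_R = c(seq(0.02, 0.09, by = 0.01), seq(0.1, 1, by = 0.05)),
        n_max = c(10, 33, 100, 333, 1000),
        lD_over_R = 1, eps_ratio = 1)),
    "screening" = list(
      kind = "free-energy-point", preset = name,
      params = expand.grid(eps_ratio = c(0, 0.1, 0.5, 1, 2),
                           lD_over_R = 10^seq(-1.25, 1.5, length.out = 9))),
    "charge-sweep" = list(
      kind = "sweep", preset = name,
      params = expand.grid(eps_ratio = c(0, 0.01, 0.1, 1),
                           s = 10^seq(-4, 1, length.out = 6)))
  )
}

#' Compute and export potential/charge profiles for a parameter scan
#'
#' For `kind = "potential"` configurations, writes one charge-profile and
#' one surface-potential CSV per parameter row.  For
#' `kind = "potential-isolated"` (fixed disk, growing cell), writes cell,
#' isolated and difference potentials on a common \eqn{r/l_D} grid, all
#' rescaled to the fixed disk charge density (so the \eqn{r_0 = R} case
#' is 1 and the \eqn{R \to \infty} case is the isolated disk).
#'
#' @param config a preset from [preset_parameters()] or a compatible list.
#' @param out_dir output directory (created if needed).
#' @param r_grid radial grid in units of R (or of `max(R/lD)` for the
#'   isolated kind).
#' @param ctrl a [series_control()].
#' @return character vector of files written, invisibly.
#' @export
run_potential_profiles <- function(config, out_dir,
                                   r_grid = seq(0, 1, length.out = 201),
                                   ctrl = series_control()) {
  params <- config$params
  if (is.null(params) || nrow(params) == 0) {
    stop("empty parameter list: nothing to run")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (identical(config$kind, "potential")) {
    for (i in seq_len(nrow(params))) {
      p <- params[i, ]
      geom <- cell_geometry(R = 1, r0 = p$r0_over_R)
      medium <- electrolyte_interface(lD = p$lD_over_R,
                                      eps_ratio = p$eps_ratio)
      tag <- sprintf("r0_%g", p$r0_over_R)
      sp <- radial_profile(r_grid, sigma_profile(r_grid, geom, ctrl),
                           "charge", params = as.list(p))
      pp <- radial_profile(r_grid,
                           surface_potential_cell(r_grid, geom, medium,
                                                  ctrl),
                           "potential", params = as.list(p))
      f1 <- file.path(out_dir, paste0("sigma_", tag, ".csv"))
      f2 <- file.path(out_dir, paste0("phi_", tag, ".csv"))
      write_profile_csv(sp, f1)
      write_profile_csv(pp, f2)
      files <- c(files, f1, f2)
    }
  } else if (identical(config$kind, "potential-isolated")) {
    RL <- params$R_over_lD
    r0_lD <- params$r0_over_lD[1]
    eps <- params$eps_ratio[1]
    medium <- electrolyte_interface(lD = 1, eps_ratio = eps)
    rmax <- max(RL[is.finite(RL)])
    grid_lD <- r_grid * rmax   # radii in units of lD
    iso_geom <- cell_geometry(R = r0_lD, r0 = r0_lD)  # disk-density scale
    iso <- surface_potential_isolated(grid_lD, iso_geom, medium)
    f <- file.path(out_dir, "phi_isolated.csv")
    write_profile_csv(radial_profile(grid_lD, iso, "potential",
                                     params = list(R_over_lD = Inf,
                                                   r0_over_lD = r0_lD,
                                                   eps_ratio = eps,
                                                   r_unit = "lD",
                                                   charge_scale = "disk")),
                      f)
    files <- c(files, f)
    for (RLi in RL[is.finite(RL)]) {
      geom <- cell_geometry(R = RLi, r0 = r0_lD)
      inside <- grid_lD <= RLi
      ## rescale cell potential from the cell-average to the disk density
      vals <- surface_potential_cell(grid_lD[inside] / RLi, geom, medium,
                                     ctrl) * (r0_lD / RLi)^2
      tag <- sprintf("RL_%g", RLi)
      pars <- list(R_over_lD = RLi, r0_over_lD = r0_lD, eps_ratio = eps,
                   r_unit = "lD", charge_scale = "disk")
      f1 <- file.path(out_dir, paste0("phi_cell_", tag, ".csv"))
      write_profile_csv(radial_profile(grid_lD[inside], vals, "potential",
                                       params = pars), f1)
      f2 <- file.path(out_dir, paste0("dphi_", tag, ".csv"))
      write_profile_csv(radial_profile(grid_lD[inside],
                                       vals - iso[inside],
                                       "potential_difference",
                                       params = pars), f2)
      files <- c(files, f1, f2)
    }
  } else {
    stop("config kind ", config$kind, " is not a profile scan")
  }
  invisible(files)
}

#' Compute and export free-energy records for a parameter scan
#'
#' Handles the `"free-energy"` (fixed truncation grid), `"free-energy-point"`
#' (point-charge limit) and `"sweep"` (scaled \eqn{f_s(s)}) kinds.  All
#' records share the column layout
#' `(s, fs, fs_continuum, F_over_F0, eps_ratio, lD_over_R, n_max_used,
#' r0_used, convergence_estimate)`; `s`/`fs` are `NA` for non-sweep rows.
#'
#' @param config a preset from [preset_parameters()] or a compatible list;
#'   a single-point run is `list(kind = "free-energy", params =
#'   data.frame(r0_over_R =, n_max =, lD_over_R =, eps_ratio =))`.
#' @param out_file output CSV path.
#' @param rel_tol tolerance for point-charge/sweep computations.
#' @return the records data frame, invisibly; the file is written as a
#'   side effect.
#' @export
run_free_energy <- function(config, out_file, rel_tol = 1e-4) {
  params <- config$params
  if (is.null(params) || nrow(params) == 0) {
    stop("empty parameter list: nothing to run")
  }
  rec <- function(s, fs, fe, eps, lam) {
    data.frame(s = s, fs = fs, fs_continuum = if (is.na(s)) NA else s^2,
               F_over_F0 = fe$ratio, eps_ratio = eps, lD_over_R = lam,
               n_max_used = fe$n_max_used, r0_used = fe$r0_used,
               convergence_estimate = fe$convergence_estimate)
  }
  rows <- switch(config$kind,
    "free-energy" = lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      fe <- free_energy_ratio(
        cell_geometry(R = 1, r0 = p$r0_over_R),
        electrolyte_interface(lD = p$lD_over_R, eps_ratio = p$eps_ratio),
        series_control(n_max = p$n_max))
      rec(NA, NA, fe, p$eps_ratio, p$lD_over_R)
    }),
    "free-energy-point" = lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      fe <- point_charge_free_energy(
        R = 1, electrolyte_interface(lD = p$lD_over_R,
                                     eps_ratio = p$eps_ratio),
        rel_tol = rel_tol)
      rec(NA, NA, fe, p$eps_ratio, p$lD_over_R)
    }),
    "sweep" = lapply(unique(params$eps_ratio), function(eps) {
      scaled_sweep(sort(params$s[params$eps_ratio == eps]), eps,
                   rel_tol = rel_tol)
    }),
    stop("config kind ", config$kind, " is not a free-energy scan")
  )
  out <- do.call(rbind, lapply(rows, as.data.frame))
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  write_sweep_csv(out, out_file,
                  metadata = list(kind = config$kind,
                                  preset = config$preset %||% "custom",
                                  rel_tol = rel_tol))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
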