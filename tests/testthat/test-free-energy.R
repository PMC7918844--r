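test_that("free energy limits: screened-out charges and the exact total-energy identity", {
  ## strong screening kills the interaction
  fe <- free_energy_ratio(cell_geometry(R = 1, r0 = 0.01),
                          electrolyte_interface(lD = 0.05, eps_ratio = 0),
                          series_control(rel_tol = 1e-5))
  expect_lt(abs(fe$ratio), 1e-3)

  ## keeping the self-energy at r0 = R gives the continuum value exactly
  fe1 <- free_energy_ratio(cell_geometry(R = 1, r0 = 1), medium_unit(1),
                           series_control(n_max = 500),
                           interaction_only = FALSE)
  expect_lt(abs(fe1$ratio - 1), 1e-12)
})

test_that("the paired mode sum matches direct quadrature of sigma times the neighbour potential", {
  cases <- list(
    list(rho = 0.02, lam = 1, eta = 1, n_max = 1000),
    list(rho = 0.1, lam = 0.5, eta = 0.5, n_max = 1000),
    list(rho = 0.05, lam = 2, eta = 0, n_max = 1000))
  for (cs in cases) {
    g <- cell_geometry(R = 1, r0 = cs$rho)
    m <- electrolyte_interface(lD = cs$lam, eps_ratio = cs$eta)
    fe <- free_energy_ratio(g, m, series_control(n_max = cs$n_max))
    oracle <- dhcell:::.free_energy_by_quadrature(g, m)
    expect_equal(fe$ratio, oracle, tolerance = 5e-3)
  }
})

test_that("truncation is stable once n_max exceeds five cells per disk radius", {
  g <- cell_geometry(R = 1, r0 = 0.1)
  m <- medium_unit(1)
  f50 <- free_energy_ratio(g, m, series_control(n_max = 50))
  f100 <- free_energy_ratio(g, m, series_control(n_max = 100))
  expect_lt(abs(f100$ratio - f50$ratio), 1e-3)
  expect_lt(f100$convergence_estimate, f50$convergence_estimate)
})

test_that("the point-charge limit is flat in disk radius and ordered in the dielectric ratio", {
  m <- medium_unit(1)
  f1 <- free_energy_ratio(cell_geometry(R = 1, r0 = 0.01), m,
                          series_control(n_max = 1000))$ratio
  f2 <- free_energy_ratio(cell_geometry(R = 1, r0 = 0.02), m,
                          series_control(n_max = 1000))$ratio
  expect_lt(abs(f2 - f1) / 0.01, 0.05)

  vals <- vapply(c(0, 0.5, 1, 2), function(eta) {
    point_charge_free_energy(1, electrolyte_interface(lD = 1,
                                                      eps_ratio = eta),
                             rel_tol = 1e-3)$ratio
  }, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0))

  ## weak screening: the continuum is recovered (linear extrapolation
  ## in R/lD)
  lams <- c(30, 100, 300)
  ratios <- vapply(lams, function(lam) {
    point_charge_free_energy(1, electrolyte_interface(lD = lam,
                                                      eps_ratio = 1),
                             rel_tol = 1e-3)$ratio
  }, 0)
  ext <- unname(coef(lm(ratios ~ I(1 / lams)))[1])
  expect_equal(ext, 1, tolerance = 0.02)

  ## diagnostics are populated
  fe <- point_charge_free_energy(1, m, rel_tol = 1e-3)
  expect_lt(fe$r0_used, 0.05)
  expect_gt(fe$n_max_used, 5 / 0.05)
  expect_true(is.finite(fe$convergence_estimate))
  expect_gte(length(fe$iterates), 2)
})

test_that("scaled sweeps carry the continuum reference and its exponential suppression at eps_l = 0", {
  sw <- scaled_sweep(c(1e-3, 1e-2), eps_ratio = 0, rel_tol = 1e-3)
  expect_identical(sw$fs_continuum, sw$s^2)
  expect_identical(sw$fs, sw$F_over_F0 * sw$s^2)
  ## without a field in the lower medium the interaction is screened out:
  ## fs collapses far below the continuum s^2 law at small s
  expect_lt(sw$F_over_F0[sw$s == 1e-3], 1e-4)
  expect_error(scaled_sweep(c(-1, 1), 1), "> 0")
})

test_that("log-log slopes recover exact power laws", {
  s <- c(1e-4, 1e-3, 1e-2)
  expect_equal(loglog_slope(s, s^2.5), 2.5, tolerance = 1e-10)
  expect_equal(loglog_slope(s, s^2), 2, tolerance = 1e-10)
  expect_equal(loglog_slope(s, rep(3.7, 3)), 0, tolerance = 1e-10)
  expect_error(loglog_slope(s, c(1, -1, 1)), "positive")
  expect_error(loglog_slope(c(1, 1), c(1, 2)), "distinct")
  expect_error(loglog_slope(1, 1), "at least two")
})

test_that("physical-unit conversion reproduces the continuum free-energy scale", {
  ## salt density chosen so that lD = 1 nm exactly
  cst <- dhcell:::.dh_constants
  n0 <- 80 * cst$eps0 * cst$kB * 298 / (2 * cst$e^2 * (1e-9)^2)
  m <- electrolyte_interface(lD = 1e-9, eps_ratio = 1, eps_w = 80,
                             temperature = 298, n0 = n0)
  expect_equal(debye_length(80, 298, n0), 1e-9, tolerance = 1e-12)
  ## an inconsistent Debye length is rejected
  expect_error(electrolyte_interface(lD = 2e-9, eps_ratio = 1, eps_w = 80,
                                     temperature = 298, n0 = n0),
               "inconsistent")

  R <- 2e-9
  fe <- free_energy_ratio(cell_geometry(R = R, r0 = R), m,
                          series_control(n_max = 200),
                          interaction_only = FALSE)  # F/F0 = 1 exactly
  ph <- to_physical_units(fe, m)
  sigma0 <- cst$e / (pi * R^2)
  expect_equal(ph$F_per_area, sigma0^2 * 1e-9 / (2 * 80 * cst$eps0),
               tolerance = 1e-12)

  ## halving the cell area doubles sigma0 and quadruples F/A
  fe2 <- free_energy_ratio(cell_geometry(R = R / sqrt(2), r0 = R / sqrt(2)),
                           m, series_control(n_max = 200),
                           interaction_only = FALSE)
  ph2 <- to_physical_units(fe2, m)
  expect_equal(ph2$F_per_area / ph$F_per_area, 4, tolerance = 1e-12)

  expect_error(to_physical_units(fe, medium_unit(1)), "physical block")
})
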