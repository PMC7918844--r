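test_that("the far-field asymptote has its stated closed form", {
  m0 <- electrolyte_interface(lD = 1, eps_ratio = 0)
  expect_equal(hurd_asymptotic(2, m0), 0.5 * exp(-2) / 2, tolerance = 1e-14)

  m1 <- medium_unit(1)
  expect_equal(hurd_asymptotic(1, m1), 0.5 * (exp(-1) + 1),
               tolerance = 1e-14)

  ## dipole scaling: r^-3 once the screened term is negligible
  ratio <- hurd_asymptotic(20, m1) / hurd_asymptotic(40, m1)
  expect_equal(ratio, 8, tolerance = 1e-5)

  expect_error(hurd_asymptotic(0, m1), "> 0")
})

test_that("disk potential decays, matches brute-force quadrature and the screened-Coulomb limit", {
  ## genuinely screened decay only when the lower medium carries no field
  g <- cell_geometry(R = 1, r0 = 1)
  m0 <- electrolyte_interface(lD = 1, eps_ratio = 0)
  expect_lt(abs(surface_potential_isolated(30, g, m0)), 1e-6)
  ## with eps_l > 0 the tail is algebraic (dipolar), ~ (1/2) eta / r^3
  m1 <- medium_unit(1)
  v30 <- surface_potential_isolated(30, g, m1)
  expect_lt(abs(v30), 1e-4)
  expect_equal(v30, hurd_asymptotic(30, m1), tolerance = 0.01)

  ## oscillation-aware quadrature vs fine-grid trapezoid (cut off at a
  ## zero of the oscillatory factor far enough out that the remaining
  ## tail is below the comparison tolerance)
  v <- surface_potential_isolated(0.5, cell_geometry(R = 1, r0 = 0.3), m1)
  vb <- trapezoid_disk_potential(0.5, 0.3, 1, 1, y_max = 3993.1, n = 2e7)
  expect_equal(v, vb, tolerance = 1e-6)

  ## small disk, eps_l = 0: pure screened Coulomb at r = 5 lD
  vs <- surface_potential_isolated(5, cell_geometry(R = 1, r0 = 0.01), m0)
  expect_equal(vs, 0.5 * exp(-5) / 5, tolerance = 0.05)

  expect_error(surface_potential_isolated(-1, g, m1), ">= 0")
})

test_that("the point-charge integral matches its limits and scalings", {
  m1 <- medium_unit(1)
  ## r0 -> 0 consistency at r = lD
  pt <- surface_potential_point_isolated(1, m1)
  disk <- surface_potential_isolated(1, cell_geometry(R = 1, r0 = 1e-3), m1,
                                     n_panels = 300L)
  expect_equal(pt, disk, tolerance = 5e-3)

  ## far field against the screened-Coulomb + dipole asymptote
  m001 <- electrolyte_interface(lD = 1, eps_ratio = 0.01)
  still <- surface_potential_point_isolated(20, m001)
  expect_equal(still, hurd_asymptotic(20, m001), tolerance = 0.05)

  ## the normalisation radius enters as a pure R^2 prefactor
  expect_equal(surface_potential_point_isolated(2, m1, R_scale = 3) /
                 surface_potential_point_isolated(2, m1, R_scale = 1),
               9, tolerance = 1e-12)

  expect_error(surface_potential_point_isolated(0, m1), "diverges")
})

test_that("the dipole tail has slope -3 where it dominates", {
  ## at eps_ratio = 0.1 the dipole dominates from ~10 lD on; at 0.01 the
  ## screened-Coulomb term still contributes at 10 lD, so start at 20 lD
  m <- electrolyte_interface(lD = 1, eps_ratio = 0.1)
  rs <- exp(seq(log(10), log(40), length.out = 5))
  sl <- loglog_slope(rs, surface_potential_point_isolated(rs, m))
  expect_equal(sl, -3, tolerance = 0.1)

  m2 <- electrolyte_interface(lD = 1, eps_ratio = 0.01)
  rs2 <- exp(seq(log(20), log(40), length.out = 4))
  sl2 <- loglog_slope(rs2, surface_potential_point_isolated(rs2, m2))
  expect_equal(sl2, -3, tolerance = 0.1)
})

test_that("cell and isolated potentials agree for large cells", {
  m1 <- medium_unit(1)
  iso <- surface_potential_isolated(0, cell_geometry(R = 1, r0 = 1), m1)
  ## disk-density scaling: multiply the cell value by (r0/R)^2
  cells <- vapply(c(4, 8, 16), function(RL) {
    surface_potential_cell(0, cell_geometry(R = RL, r0 = 1), m1,
                           series_control(n_max = 30000)) / RL^2
  }, 0)
  expect_equal(cells[3], iso, tolerance = 0.01)
  ait <- cells[3] - (cells[3] - cells[2])^2 /
    ((cells[3] - cells[2]) - (cells[2] - cells[1]))
  expect_equal(ait, iso, tolerance = 5e-3)
})

test_that("the difference potential isolates the neighbours' field", {
  m1 <- medium_unit(1)
  ## r0 = R = lD: the cell part is exactly 1
  g <- cell_geometry(R = 1, r0 = 1)
  grid <- seq(0, 1, length.out = 21)
  d <- delta_surface_potential(grid, g, m1, series_control(n_max = 200))
  iso <- surface_potential_isolated(grid, g, m1)
  expect_equal(d$value, 1 - iso, tolerance = 1e-8)
  expect_identical(attr(d, "kind"), "potential_difference")

  ## neighbours always raise the potential here (all curves positive)
  for (RL in c(1.5, 4)) {
    gR <- cell_geometry(R = RL, r0 = 1)
    dR <- delta_surface_potential(seq(0, 1, length.out = 21), gR, m1,
                                  series_control(n_max = 20000))
    expect_true(all(dR$value > 0))
  }

  ## very large cell: neighbours contribute less than 1% of the self term
  g16 <- cell_geometry(R = 16, r0 = 1)
  d16 <- delta_surface_potential(seq(0, 1, length.out = 9), g16, m1,
                                 series_control(n_max = 30000))
  self0 <- surface_potential_isolated(0, g16, m1)
  expect_lt(max(abs(d16$value)), 0.01 * self0)
})
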