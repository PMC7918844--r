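test_that("a disk filling the cell gives unit surface potential exactly", {
  g <- cell_geometry(R = 1, r0 = 1)
  for (lam in c(0.05, 1, 20)) {
    for (eta in c(0, 1, 2.5)) {
      m <- electrolyte_interface(lD = lam, eps_ratio = eta)
      v <- surface_potential_cell(c(0, 0.3, 0.7, 1), g, m,
                                  series_control(n_max = 300))
      expect_true(all(abs(v - 1) < 1e-12))
    }
  }
})

test_that("charge-profile partial sums reproduce the step profile", {
  g <- cell_geometry(R = 1, r0 = 0.4)
  ctrl <- series_control(n_max = 4000)
  ## inside the disk: sigma-bar/sigma0 = (R/r0)^2
  expect_equal(sigma_profile(0, g, ctrl), 6.25, tolerance = 0.02)
  ## at the step: the series converges to the Heaviside half value
  expect_equal(sigma_profile(0.4, g, ctrl), 6.25 / 2, tolerance = 0.005)
  ## outside: zero up to the Gibbs tail
  expect_lt(abs(sigma_profile(0.8, g, ctrl)), 0.05)

  ## cell average of the profile is the average density (Simpson rule on
  ## a grid fine enough to resolve the n_max = 500 oscillation)
  ctrl500 <- series_control(n_max = 500)
  ngrid <- 40001
  x <- seq(0, 1, length.out = ngrid)
  fx <- x * sigma_profile(x, g, ctrl500)
  h <- x[2] - x[1]
  w <- rep(c(2, 4), length.out = ngrid)
  w[c(1, ngrid)] <- 1
  avg <- 2 * sum(w * fx) * h / 3
  expect_equal(avg, 1, tolerance = 1e-6)
})

test_that("surface potential is monotone in the dielectric ratio and scale invariant", {
  g <- cell_geometry(R = 1, r0 = 0.4)
  vals <- vapply(c(0, 0.5, 1, 2), function(eta) {
    surface_potential_cell(0.3, g, electrolyte_interface(lD = 1,
                                                         eps_ratio = eta),
                           series_control(n_max = 2000))
  }, 0)
  expect_true(all(diff(vals) < 0))

  ## joint rescaling of (R, r0, lD) leaves the scaled potential unchanged
  k <- 7
  a <- surface_potential_cell(0.35, cell_geometry(R = 1, r0 = 0.4),
                              electrolyte_interface(lD = 0.8, eps_ratio = 1),
                              series_control(n_max = 1500))
  b <- surface_potential_cell(0.35, cell_geometry(R = k, r0 = 0.4 * k),
                              electrolyte_interface(lD = 0.8 * k,
                                                    eps_ratio = 1),
                              series_control(n_max = 1500))
  expect_identical(a, b)
})

test_that("point-charge series agrees with a small disk and diverges at the origin", {
  m <- medium_unit(1)
  pt <- surface_potential_point_cell(1, m, series_control(n_max = 2000))
  disk <- surface_potential_cell(1, cell_geometry(R = 1, r0 = 1e-3), m,
                                 series_control(n_max = 20000))
  expect_equal(pt, disk, tolerance = 5e-3)

  expect_error(surface_potential_point_cell(0, m,
                                            series_control(n_max = 100)),
               "diverges")
  expect_error(surface_potential_point_cell(0.5, m, series_control()),
               "explicit")

  ## strong screening: the cell-edge value vanishes (tail-averaged series;
  ## the plain partial sums oscillate at the 0.05 level here)
  m2 <- electrolyte_interface(lD = 0.05, eps_ratio = 0)
  v <- surface_potential_point_cell(1, m2, series_control(n_max = 20000),
                                    tail_average = TRUE)
  expect_lt(abs(v), 1e-4)
})

test_that("the dielectric-jump condition and cell-edge symmetry hold", {
  g <- cell_geometry(R = 1, r0 = 0.4)
  m <- electrolyte_interface(lD = 0.7, eps_ratio = 1.3)
  ctrl <- series_control(n_max = 800)
  x <- c(0, 0.2, 0.55, 0.9)
  dz_up <- potential_field(x, 0, g, m, ctrl, derivative = "dz",
                           branch = "electrolyte")
  dz_dn <- potential_field(x, 0, g, m, ctrl, derivative = "dz",
                           branch = "dielectric")
  lam <- m$lD
  sig <- sigma_profile(x, g, ctrl)
  ## eps_w dPhi1/dz - eps_l dPhi2/dz = -sigma/eps0, scaled mode by mode
  expect_equal(-lam * (dz_up - m$eps_ratio * dz_dn), sig,
               tolerance = 1e-10)

  ## radial derivative of the surface potential vanishes at the cell edge
  h <- 1e-4
  phi <- surface_potential_cell(c(1 - 2 * h, 1 - h, 1), g, m,
                                series_control(n_max = 4000))
  dphi <- (3 * phi[3] - 4 * phi[2] + phi[1]) / (2 * h)
  expect_lt(abs(dphi), 5e-3 * max(abs(phi)))
})

test_that("the field is continuous at the interface and decays away from it", {
  g <- cell_geometry(R = 1, r0 = 0.4)
  m <- medium_unit(1)
  ctrl <- series_control(n_max = 1000)
  x <- c(0, 0.3, 0.8)
  up0 <- potential_field(x, 0, g, m, ctrl, branch = "electrolyte")
  dn0 <- potential_field(x, 0, g, m, ctrl, branch = "dielectric")
  expect_equal(up0, dn0, tolerance = 1e-12)

  ## screened side: even the slowest mode decays at least like exp(-z/lD)
  up5 <- potential_field(x, 5, g, m, ctrl)
  expect_true(all(abs(up5) < exp(-5) * max(abs(up0))))

  ## salt-free side: all decaying modes gone far below, only the constant
  ## Laplace mode survives
  dn8 <- potential_field(x, -8, g, m, ctrl)
  expect_true(all(abs(dn8 - 1) < 1e-3))
})
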