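test_that("moment arm is minus the length derivative", {
  const <- muscle_params("const", 100, length_poly = 0.3, l_opt = 0.1, l_slack = 0.19)
  for (th in c(-1, 0, 0.5, 2)) expect_identical(moment_arm(const, th), 0)

  lin <- muscle_params("lin", 100, length_poly = c(0.3, -0.03), l_opt = 0.1,
                       l_slack = 0.15)
  expect_equal(moment_arm(lin, 0.2), 0.03)
  expect_equal(moment_arm(lin, 2.0), 0.03)

  # central finite-difference oracle on every forearm muscle
  fm <- fixture_forearm()
  eps <- 1e-5
  for (mu in fm$muscles) {
    for (th in c(0.3, 1.0, 2.2)) {
      fd <- -(musculotendon_length(mu, th + eps) -
                musculotendon_length(mu, th - eps)) / (2 * eps)
      expect_equal(moment_arm(mu, th), fd, tolerance = 1e-6)
    }
  }
})

test_that("moment arm respects the configured joint range", {
  fm <- fixture_forearm()
  expect_error(moment_arm(fm$muscles[[1]], 3.2), "range")
  expect_error(moment_arm(fm$muscles[[1]], -0.5), "range")
})

test_that("force-length curve is a unit-peak Gaussian", {
  expect_equal(force_length(1), 1.0)
  expect_equal(force_length(1 + sqrt(0.45)), exp(-1))
  xs <- seq(0.05, 0.6, by = 0.11)
  expect_equal(force_length(1 + xs), force_length(1 - xs))
  expect_error(force_length(0), "positive")
  expect_error(force_length(-0.2), "positive")
})

test_that("force-velocity curve has Hill-type endpoints and monotonicity", {
  expect_equal(force_velocity(0), 1.0)
  expect_equal(force_velocity(-1), 0.0)
  fv_len <- force_velocity(0.5)
  expect_gt(fv_len, 1); expect_lte(fv_len, 1.4)
  grid <- seq(-1.2, 2, by = 0.02)
  vals <- force_velocity(grid)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals <= 1.4 + 1e-12))
  # activation dependence only acts when switched on
  expect_equal(force_velocity(-0.3, a = 0.1), force_velocity(-0.3, a = 0.9))
  expect_lt(force_velocity(-0.3, a = 0.1, a_dependence = TRUE),
            force_velocity(-0.3, a = 0.9, a_dependence = TRUE))
})

test_that("muscle force follows the Hill product and is linear in activation", {
  iso <- muscle_params("iso", F0max = 250, length_poly = 0.3, l_opt = 0.1,
                       l_slack = 0.2)  # l_norm = 1, zero moment arm
  expect_equal(muscle_force(iso, 0, 0, a = 1), 250)
  expect_equal(muscle_force(iso, 0.7, 0, a = 0), 0)

  fm <- fixture_forearm()
  for (mu in fm$muscles) {
    expect_equal(muscle_force(mu, 1.1, 0, a = 0), 0)
    f_half <- muscle_force(mu, 1.1, 1.5, a = 0.5)
    f_full <- muscle_force(mu, 1.1, 1.5, a = 1.0)
    expect_equal(f_half, f_full / 2)
  }
})

test_that("h_analytic matches force times moment arm and tracks its sign", {
  fm <- fixture_forearm()
  thetas <- seq(0.05, 2.55, length.out = 23)
  for (mu in fm$muscles) {
    h0 <- vapply(thetas, function(th) h_analytic(mu, th, 0), numeric(1))
    fr <- vapply(thetas, function(th)
      muscle_force(mu, th, 0, a = 1) * moment_arm(mu, th), numeric(1))
    expect_equal(h0, fr)
    r <- vapply(thetas, function(th) moment_arm(mu, th), numeric(1))
    expect_identical(sign(h0), sign(r))
  }
  # zero moment arm -> zero h: quadratic length poly with extremum at theta0
  theta0 <- 0.8
  hump <- muscle_params("hump", 100, length_poly = c(0.3, -0.02 * theta0, 0.01),
                        l_opt = 0.1, l_slack = 0.19)
  expect_lt(abs(moment_arm(hump, theta0)), 1e-12)
  expect_lt(abs(h_analytic(hump, theta0, 1.0)), 1e-12)
})

test_that("h is insensitive to activation when the a-dependence is enabled", {
  fm <- fixture_forearm(fv_a_dependence = TRUE)
  bic <- fm$muscles[[muscle_index(fm, "biceps_long")]]
  thetas <- seq(0.1, 2.5, length.out = 15)
  a_grid <- seq(0, 1, length.out = 21)
  rel_change <- vapply(thetas, function(th) {
    hs <- vapply(a_grid, function(a) h_analytic(bic, th, 2, a_ref = a), numeric(1))
    (max(hs) - min(hs)) / max(abs(hs))
  }, numeric(1))
  expect_lt(max(rel_change), 0.6)  # configured flatness bound
})
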