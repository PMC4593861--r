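test_that("torque-probe h agrees with the analytic transform", {
  fm <- fixture_forearm()
  grid <- seq(fm$theta_range[1] + 0.01, fm$theta_range[2] - 0.01, length.out = 20)
  for (th in grid) {
    ha <- h_vector(fm, th)
    hp <- vapply(seq_along(fm$muscles), function(i) probe_h(fm, i, th), numeric(1))
    expect_equal(unname(ha), hp, tolerance = 1e-10)
  }
  # probing subtracts gravity/damping baselines
  cm <- make_crank_model(3, include_gravity = TRUE)
  expect_equal(probe_h(cm, 1, 0.5), unname(h_vector(cm, 0.5)[1]), tolerance = 1e-8)
  expect_error(probe_h(fm, 1, 5), "range")
  expect_error(probe_h(fm, 1, 1, a_probe = 0), "a_probe")
})

test_that("synergy tables have unit representatives and one-sided ratios", {
  fm <- fixture_forearm()
  tab <- build_synergy_table(fm, theta_grid = seq(0, 2.6, length.out = 41))
  expect_true(all(tab$S_pos[, tab$rep_pos] == 1))
  expect_true(all(tab$S_neg[, tab$rep_neg] == 1))
  expect_true(all(tab$S_pos >= 0) && all(tab$S_neg >= 0))
  expect_true(all(tab$S_pos * tab$S_neg == 0))  # one synergy per muscle per posture
  # extensor heads never join the flexor synergy, and vice versa
  tri <- grep("^triceps", tab$muscle_names)
  expect_true(all(tab$S_pos[, tri] == 0))
  expect_true(all(tab$S_neg[, tri] > 0))
  flex <- setdiff(seq_along(tab$muscle_names), tri)
  expect_true(all(tab$S_neg[, flex] == 0))
})

test_that("a sign-switching muscle changes synergy across its zero crossing", {
  cm <- fixture_crank(42)
  tab <- build_synergy_table(cm, theta_grid = seq(-pi / 2, pi / 2, length.out = 61))
  sw <- attr(cm, "switch_index")
  expect_true(any(tab$S_pos[, sw] > 0))
  expect_true(any(tab$S_neg[, sw] > 0))
  # membership is one-sided in theta: pos side and neg side do not interleave
  pos_idx <- which(tab$S_pos[, sw] > 0)
  neg_idx <- which(tab$S_neg[, sw] > 0)
  expect_true(max(pos_idx) < min(neg_idx) || max(neg_idx) < min(pos_idx))
})

test_that("representative validation rejects sign-switching candidates", {
  cm <- fixture_crank(42)
  grid <- seq(cm$theta_range[1], cm$theta_range[2], length.out = 51)
  expect_silent(validate_representatives(cm, grid, cm$rep_pos, cm$rep_neg))
  sw <- attr(cm, "switch_index")
  err <- tryCatch(validate_representatives(cm, grid, sw, cm$rep_neg),
                  error = function(e) e)
  expect_s3_class(err, "invalid_representative")
  expect_match(conditionMessage(err), "theta")  # names the posture of failure
  expect_error(validate_representatives(cm, numeric(0), 1, 2), "non-empty")
  expect_error(validate_representatives(cm, c(1, 0.5), 1, 2), "increasing")
  expect_error(build_synergy_table(cm, rep_pos = sw, rep_neg = cm$rep_neg),
               class = "invalid_representative")
})

test_that("reconstruction reads out synergy columns and interpolates", {
  fm <- fixture_forearm()
  grid <- seq(0, 2.6, length.out = 41)
  tab <- build_synergy_table(fm, theta_grid = grid)
  expect_identical(unname(reconstruct_activations(tab, 0, 0, 1.3)), rep(0, 7))
  k <- 17
  expect_equal(unname(reconstruct_activations(tab, 1, 0, grid[k])),
               unname(tab$S_pos[k, ]))
  expect_equal(unname(reconstruct_activations(tab, 0, 0.7, grid[k])),
               unname(0.7 * tab$S_neg[k, ]))
  mid <- (grid[5] + grid[6]) / 2
  expect_equal(unname(reconstruct_activations(tab, 1, 0, mid)),
               unname((tab$S_pos[5, ] + tab$S_pos[6, ]) / 2))
  expect_error(reconstruct_activations(tab, -0.1, 0, 1), "nonnegative")
  expect_error(reconstruct_activations(tab, 1, 0, 3.5), "span")
})

test_that("synergy reconstruction reproduces the closed-form optimum", {
  fm <- fixture_forearm()
  tab <- build_synergy_table(fm)
  thetas <- seq(0.1, 2.5, length.out = 9)
  torques <- c(-4, -1.5, 2, 5)
  for (th in thetas) for (T_d in torques) {
    h <- h_vector(fm, th)
    a_opt <- optimal_activations(h, T_d)
    if (T_d > 0) {
      a_rec <- reconstruct_activations(tab, a_opt[tab$rep_pos], 0, th)
    } else {
      a_rec <- reconstruct_activations(tab, 0, a_opt[tab$rep_neg], th)
    }
    expect_equal(unname(a_rec), unname(a_opt), tolerance = 0.02)
    expect_equal(sum(a_rec * h), T_d, tolerance = 0.02 * abs(T_d))
  }
})

test_that("mirrored models swap synergy roles", {
  cm <- fixture_crank(11)
  mirror <- one_dof_model(
    lapply(cm$muscles, function(mu) {
      cf <- mu$length_poly
      cf[seq(2, length(cf), by = 2)] <- -cf[seq(2, length(cf), by = 2)]
      mu2 <- mu; mu2$length_poly <- cf
      do.call(muscle_params, mu2[c("name", "F0max", "length_poly", "l_opt",
                                   "l_slack", "pennation", "v_max", "fl_width",
                                   "fv_shape", "fv_ceiling", "fv_a_dependence",
                                   "theta_range")])
    }),
    inertia = 0.1, theta_range = cm$theta_range, damping = cm$damping,
    rep_pos = cm$rep_neg, rep_neg = cm$rep_pos, name = "mirror")
  # l_mirror(theta) = l(-theta) => h_mirror(theta) = -h(-theta)
  grid <- seq(-1.5, 1.5, length.out = 21)
  tab <- build_synergy_table(cm, theta_grid = grid)
  tabm <- build_synergy_table(mirror, theta_grid = grid)
  expect_equal(tabm$S_pos, tab$S_neg[rev(seq_along(grid)), ], tolerance = 1e-10)
  expect_equal(tabm$S_neg, tab$S_pos[rev(seq_along(grid)), ], tolerance = 1e-10)
})

test_that("velocity-dependent tables interpolate bilinearly", {
  fm <- fixture_forearm(fv_a_dependence = FALSE)
  tab <- build_synergy_table(fm, theta_grid = seq(0.2, 2.4, length.out = 11),
                             use_theta_dot = TRUE,
                             theta_dot_grid = seq(-2, 2, length.out = 5))
  a <- reconstruct_activations(tab, 1, 0, 1.3, theta_dot = 0.7)
  h <- h_vector(fm, 1.3, 0.7)
  expect_equal(unname(a[h > 0] / a[tab$rep_pos]),
               unname(h[h > 0] / h[tab$rep_pos]), tolerance = 0.01)
})

test_that("synergy tables round-trip through JSON and export to CSV", {
  fm <- fixture_forearm()
  tab <- build_synergy_table(fm, theta_grid = seq(0, 2.6, length.out = 21))
  path <- withr::local_tempfile(fileext = ".json")
  write_synergy_table(tab, path)
  back <- read_synergy_table(path)
  expect_equal(back$S_pos, tab$S_pos)
  expect_equal(back$S_neg, tab$S_neg)
  expect_equal(back$theta_grid, tab$theta_grid)
  expect_identical(back$muscle_names, tab$muscle_names)
  a1 <- reconstruct_activations(tab, 0.4, 0, 1.1)
  a2 <- reconstruct_activations(back, 0.4, 0, 1.1)
  expect_equal(a1, a2)

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- synergy_table_to_df(tab, csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv)), 21 * 7)
})
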