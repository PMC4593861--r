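test_that("PID law: linearity, Table-style gain, saturation", {
  cfg <- pid_config(Kp = 10, Ki = 10, Kd = 2)
  expect_equal(pid_step(cfg, 0, 0, 0), 0)
  expect_equal(pid_step(pid_config(Kp = 10, Ki = 0, Kd = 0), 0.05), 0.5)
  expect_equal(pid_step(cfg, 1, 0, 0), 1)
  expect_equal(pid_step(cfg, -1, 0, 0), -1)
  expect_error(pid_config(Kp = -1), "nonnegative")
})

test_that("signed activation splits into exclusive synergy drives", {
  expect_equal(split_signed_activation(0.3), c(pos = 0.3, neg = 0))
  expect_equal(split_signed_activation(-0.2), c(pos = 0, neg = 0.2))
  expect_equal(split_signed_activation(0), c(pos = 0, neg = 0))
  expect_error(split_signed_activation(1.5), "\\[-1, 1\\]")
})

test_that("trajectories are seeded, smooth and range-respecting", {
  t1 <- trajectory_spec(seed = 3, duration = 5, theta_range = c(0, 2.6))
  t2 <- trajectory_spec(seed = 3, duration = 5, theta_range = c(0, 2.6))
  expect_identical(t1, t2)
  ts <- seq(0, 5, by = 0.01)
  tr <- trajectory_eval(t1, ts)
  expect_true(all(tr$theta >= 0 & tr$theta <= 2.6))
  # derivative consistency by finite differences
  eps <- 1e-6
  mid <- trajectory_eval(t1, 2.5)
  fd <- (trajectory_eval(t1, 2.5 + eps)$theta -
           trajectory_eval(t1, 2.5 - eps)$theta) / (2 * eps)
  expect_equal(mid$theta_dot, fd, tolerance = 1e-5)
  expect_error(trajectory_spec(seed = 1, duration = 5, theta_range = c(0, 2.6),
                               offset = 2.5), "range")
})

test_that("FSO at equilibrium on target produces near-zero activations", {
  toy <- fixture_toy(damping = 0.1)
  a <- fso_step(toy, list(theta = 0.2, theta_dot = 0), 0.2, 0)
  expect_true(all(abs(a) < 1e-6))
})

test_that("FSO with dominant tracking weights recovers the sharing optimum", {
  fm <- fixture_forearm()
  state <- list(theta = 1.1, theta_dot = 0.4)
  cfg <- fso_config(w1 = 1, w2 = 1e10, w3 = 1e10)
  a <- fso_step(fm, state, 1.102, 0.5, cfg, dt = 1e-3)
  h <- h_vector(fm, state$theta, state$theta_dot)
  T_implied <- sum(a * h)
  a_opt <- suppressWarnings(optimal_activations(h, T_implied))
  expect_equal(unname(a), unname(a_opt), tolerance = 1e-6)
  expect_gt(abs(T_implied), 0)
})

test_that("effort is the time-averaged summed squared activation", {
  fake <- function(acts, t) structure(
    list(time = t, activations = acts, theta = t * 0, theta_des = t * 0),
    class = "simulation_result")
  t <- seq(0, 4, by = 0.01)
  expect_equal(effort(fake(matrix(0, length(t), 3), t)), 0)
  expect_equal(effort(fake(matrix(0.5, length(t), 1), t)), 0.25)
  two <- cbind(rep(0.3, length(t)), rep(0.4, length(t)))
  expect_equal(effort(fake(two, t)), 0.25)
  expect_error(effort(fake(matrix(0, 1, 1), 0)), "duration")
})

test_that("synergy-PID tracks the forearm task with bounded activations", {
  fm <- fixture_forearm()
  tab <- build_synergy_table(fm)
  traj <- trajectory_spec(seed = 5, duration = 2, theta_range = fm$theta_range)
  res <- simulate_pid(fm, tab, traj)
  expect_lt(res$rms_error, 0.01)
  expect_true(all(res$activations >= 0))
  expect_true(all(res$activations <= 1))
  expect_equal(nrow(res$activations), length(res$time))
})

test_that("FSO and synergy-PID produce closely matching activation patterns", {
  fm <- fixture_forearm()
  tab <- build_synergy_table(fm)
  traj <- trajectory_spec(seed = 5, duration = 3, theta_range = fm$theta_range)
  fso <- simulate_fso(fm, traj)
  pid <- simulate_pid(fm, tab, traj)
  expect_equal(fso$solver_failures, 0L)
  for (i in seq_along(fm$muscles)) {
    x <- fso$activations[, i]; y <- pid$activations[, i]
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    cosine <- if (nx < 1e-12 && ny < 1e-12) 1 else sum(x * y) / (nx * ny)
    expect_gte(cosine, 0.9)
  }
  expect_lt(abs(pid$effort / fso$effort - 1), 0.25)
})

test_that("comparison reports are deterministic and exportable", {
  cm <- fixture_crank(4)
  traj <- trajectory_spec(seed = 6, duration = 1.5, theta_range = cm$theta_range)
  tab <- build_synergy_table(cm)
  r1 <- run_comparison(cm, traj, table = tab)
  r2 <- run_comparison(cm, traj, table = tab)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$results$fso$activations, r2$results$fso$activations)

  dir <- withr::local_tempdir()
  paths <- write_comparison(r1, dir)
  expect_true(file.exists(file.path(dir, "comparison_summary.csv")))
  expect_true(file.exists(file.path(dir, "fso_timeseries.csv")))
  js <- jsonlite::read_json(file.path(dir, "fso_summary.json"))
  expect_equal(js$effort, r1$results$fso$effort)
  expect_equal(js$rms_error, r1$results$fso$rms_error)
})

test_that("model configurations round-trip through JSON", {
  fm <- fixture_forearm()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fm, path)
  back <- read_model_json(path)
  expect_equal(comparable_model(back)$muscles, comparable_model(fm)$muscles,
               tolerance = 1e-12)
  expect_equal(h_vector(back, 1.234), h_vector(fm, 1.234), tolerance = 1e-10)
  cm <- make_crank_model(5, include_gravity = TRUE)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(cm, path2)
  back2 <- read_model_json(path2)
  expect_equal(back2$gravity(0.7), cm$gravity(0.7))
})
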