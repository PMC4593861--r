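#' PID controller configuration
#'
#' Gains act on the operational-angle tracking error and produce a *signed
#' activation* in `[-1, 1]` whose positive part drives the positive-torque
#' synergy and negative part the negative-torque synergy. Defaults are the
#' planar-model values (`Kp = 10, Ki = 10, Kd = 2`); for crank/steering tasks
#' `Kp = 100, Ki = 100, Kd = 0` are conventional.
#'
#' @param Kp,Ki,Kd Nonnegative gains.
#' @param deriv_cutoff_hz Cutoff of the first-order filter applied to the
#'   error before differentiation.
#' @return A `pid_config` object.
#' @export
pid_config <- function(Kp = 10, Ki = 10, Kd = 2, deriv_cutoff_hz = 50) {
  if (any(c(Kp, Ki, Kd) < 0)) stop("gains must be nonnegative")
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd,
                 deriv_cutoff_hz = deriv_cutoff_hz), class = "pid_config")
}

#' Forward-static-optimization controller configuration
#'
#' Weights of the per-step objective
#' `w1 * sum(a^2) + w2 * (theta - theta_des)^2 + w3 * (theta_dot - theta_dot_des)^2`
#' evaluated on a one-step forward prediction of the plant. Defaults are the
#' planar-model values (`w1 = 1, w2 = 3e6, w3 = 5e2`); `w2 = 1e4, w3 = 1e2`
#' are conventional for crank/steering tasks.
#'
#' @param w1,w2,w3 Nonnegative weights; `w1` must be positive.
#' @return An `fso_config` object.
#' @export
fso_config <- function(w1 = 1, w2 = 3e6, w3 = 5e2) {
  if (w1 <= 0) stop("w1 must be positive")
  if (any(c(w2, w3) < 0)) stop("weights must be nonnegative")
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "fso_config")
}

#' Seeded sum-of-sines trajectory specification
#'
#' A smooth random reference motion in the operational space:
#' `theta_des(t) = offset + sum_j A_j sin(2 pi f_j t + phi_j)`. When a seed is
#' given, amplitudes, frequencies (0.1-0.5 Hz) and phases are drawn so the
#' trajectory stays inside `theta_range` with total amplitude 60% of the
#' half-span — slow, sub-maximal reaching-scale motion.
#'
#' @param seed Integer seed for random components.
#' @param duration Duration, s.
#' @param theta_range Range the trajectory must respect.
#' @param n_components Number of sinusoids.
#' @param offset,amplitudes,frequencies,phases Explicit components (override
#'   the seeded draw).
#' @return A `trajectory_spec` object.
#' @export
trajectory_spec <- function(seed = NULL, duration = 10, theta_range = c(0, 2.6),
                            n_components = 3, offset = NULL, amplitudes = NULL,
                            frequencies = NULL, phases = NULL) {
  if (duration <= 0) stop("duration must be positive")
  half <- diff(theta_range) / 2
  if (is.null(offset)) offset <- mean(theta_range)
  draw <- function(expr) with_seed(seed, expr)
  if (is.null(amplitudes)) {
    if (is.null(seed)) stop("give a seed or explicit amplitudes")
    w <- draw(stats::runif(n_components, 0.5, 1))
    amplitudes <- 0.6 * half * w / sum(w)
  }
  if (is.null(frequencies)) {
    if (is.null(seed)) stop("give a seed or explicit frequencies")
    frequencies <- with_seed(seed + 1L, stats::runif(length(amplitudes), 0.1, 0.5))
  }
  if (is.null(phases)) {
    if (is.null(seed)) stop("give a seed or explicit phases")
    phases <- with_seed(seed + 2L, stats::runif(length(amplitudes), 0, 2 * pi))
  }
  lo <- offset - sum(abs(amplitudes)); hi <- offset + sum(abs(amplitudes))
  if (lo < theta_range[1] - 1e-9 || hi > theta_range[2] + 1e-9)
    stop("trajectory can leave theta_range")
  structure(list(kind = "sum_of_sines", offset = offset,
                 amplitudes = amplitudes, frequencies = frequencies,
                 phases = phases, duration = duration,
                 theta_range = theta_range),
            class = "trajectory_spec")
}

#' Evaluate a trajectory and its derivatives
#'
#' @param spec A [trajectory_spec()].
#' @param t Time(s), s.
#' @return List of vectors `theta`, `theta_dot`, `theta_ddot`.
#' @export
trajectory_eval <- function(spec, t) {
  th <- rep(spec$offset, length(t)); thd <- numeric(length(t)); thdd <- numeric(length(t))
  for (j in seq_along(spec$amplitudes)) {
    w <- 2 * pi * spec$frequencies[j]
    ph <- w * t + spec$phases[j]
    th <- th + spec$amplitudes[j] * sin(ph)
    thd <- thd + spec$amplitudes[j] * w * cos(ph)
    thdd <- thdd - spec$amplitudes[j] * w^2 * sin(ph)
  }
  list(theta = th, theta_dot = thd, theta_ddot = thdd)
}

#' One PID evaluation producing a signed activation
#'
#' `u = clamp(Kp e + Ki \int e + Kd de, -1, 1)`. The caller maintains the
#' integral and (filtered) derivative; [simulate_pid()] applies anti-windup by
#' freezing the integral while the output is saturated.
#'
#' @param config A [pid_config()].
#' @param error Tracking error, rad.
#' @param error_integral Integrated error, rad s.
#' @param error_derivative Error derivative, rad/s.
#' @return Signed activation in `[-1, 1]`.
#' @export
pid_step <- function(config, error, error_integral = 0, error_derivative = 0) {
  u <- config$Kp * error + config$Ki * error_integral + config$Kd * error_derivative
  min(max(u, -1), 1)
}

#' Split a signed activation into synergy drive levels
#'
#' @param u Signed activation in `[-1, 1]`.
#' @return Named vector `c(pos, neg)`: `(max(u, 0), max(-u, 0))`.
#' @export
split_signed_activation <- function(u) {
  if (u < -1 - 1e-12 || u > 1 + 1e-12) stop("u must be in [-1, 1]")
  c(pos = max(u, 0), neg = max(-u, 0))
}

# Synergy columns at a state, for either a posture table or static (NNMF)
# synergies.
synergy_columns <- function(syn, theta, theta_dot = 0) {
  if (inherits(syn, "synergy_table")) return(table_columns(syn, theta, theta_dot))
  if (inherits(syn, "static_synergies")) {
    if (is.null(syn$pos_col))
      stop("static synergies must be scaled to representatives first")
    return(list(pos = syn$S[, syn$pos_col], neg = syn$S[, syn$neg_col]))
  }
  stop("unsupported synergy object")
}

new_simulation_result <- function(controller, time, theta, theta_dot, theta_des,
                                  activations, torque_demand, torque_produced,
                                  solver_failures = 0L) {
  res <- structure(
    list(controller = controller, time = time, theta = theta,
         theta_dot = theta_dot, theta_des = theta_des,
         activations = activations, torque_demand = torque_demand,
         torque_produced = torque_produced, solver_failures = solver_failures),
    class = "simulation_result")
  res$effort <- effort(res)
  res$rms_error <- rms_error(res)
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s: %.1f s, effort = %.4g, RMS error = %.4g rad\n",
              x$controller, max(x$time), x$effort, x$rms_error))
  invisible(x)
}

#' Physiological effort of a simulation
#'
#' Time-averaged summed squared activation,
#' `effort = (1 / Tf) * sum_i integral(a_i^2 dt)` (trapezoidal rule).
#'
#' @param result A `simulation_result`.
#' @return Dimensionless effort.
#' @export
effort <- function(result) {
  t <- result$time
  if (length(t) < 2L || max(t) <= 0) stop("zero-duration simulation")
  s <- rowSums(result$activations^2)
  dt <- diff(t)
  sum((s[-1] + s[-length(s)]) / 2 * dt) / (t[length(t)] - t[1])
}

#' RMS operational-space tracking error
#'
#' @param result A `simulation_result`.
#' @return RMS of `theta - theta_des`, rad.
#' @export
rms_error <- function(result) {
  sqrt(mean((result$theta - result$theta_des)^2))
}

sim_times <- function(duration, dt) seq(0, duration, by = dt)

inverse_dynamics_torque <- function(model, tr) {
  model$inertia(tr$theta) * tr$theta_ddot + model$damping * tr$theta_dot -
    model$gravity(tr$theta)
}

#' Simulate synergy-driven PID tracking
#'
#' Closed-loop tracking of a reference trajectory: a PID on the angle error
#' emits a signed activation; its positive/negative parts scale the
#' positive-/negative-torque synergy columns (posture-dependent table or
#' static NNMF synergies) to produce all muscle activations, which drive the
#' plant through fixed-step RK4. Controller and integrator share the same
#' rate. The error derivative is computed on a low-pass filtered error; the
#' integral is frozen while the output saturates (anti-windup).
#'
#' @param model A [one_dof_model()].
#' @param synergies A `synergy_table` or scaled `static_synergies`.
#' @param trajectory A [trajectory_spec()].
#' @param config A [pid_config()].
#' @param dt Step size, s.
#' @param label Controller label in the result.
#' @return A `simulation_result`.
#' @export
simulate_pid <- function(model, synergies, trajectory, config = pid_config(),
                         dt = 1e-3, label = "pid") {
  times <- sim_times(trajectory$duration, dt)
  n <- length(times); m <- length(model$muscles)
  tr0 <- trajectory_eval(trajectory, 0)
  state <- list(theta = tr0$theta, theta_dot = tr0$theta_dot)
  theta <- numeric(n); theta_dot <- numeric(n); theta_des <- numeric(n)
  acts <- matrix(0, n, m); tau_dem <- numeric(n); tau_prod <- numeric(n)
  ei <- 0
  alpha <- dt / (dt + 1 / (2 * pi * config$deriv_cutoff_hz))
  ef <- NA_real_
  for (k in seq_len(n)) {
    tr <- trajectory_eval(trajectory, times[k])
    e <- tr$theta - state$theta
    if (k == 1L) { ef <- e; ed <- 0 } else {
      ef_new <- ef + alpha * (e - ef)
      ed <- (ef_new - ef) / dt
      ef <- ef_new
    }
    u_unsat <- config$Kp * e + config$Ki * (ei + e * dt) + config$Kd * ed
    if (abs(u_unsat) <= 1 || sign(u_unsat) != sign(e)) ei <- ei + e * dt
    u <- pid_step(config, e, ei, ed)
    sp <- split_signed_activation(u)
    cols <- synergy_columns(synergies, state$theta, state$theta_dot)
    a <- sp[["pos"]] * cols$pos + sp[["neg"]] * cols$neg
    theta[k] <- state$theta; theta_dot[k] <- state$theta_dot
    theta_des[k] <- tr$theta; acts[k, ] <- a
    tau_dem[k] <- inverse_dynamics_torque(model, tr)
    tau_prod[k] <- net_torque(model, state$theta, state$theta_dot, a) +
      model$damping * state$theta_dot - model$gravity(state$theta)
    if (k < n) state <- plant_step(model, state, a, dt)
  }
  colnames(acts) <- model$cache$names
  new_simulation_result(label, times, theta, theta_dot, theta_des, acts,
                        tau_dem, tau_prod)
}

#' One forward-static-optimization control step
#'
#' Minimizes `w1 sum(a^2) + w2 (theta+ - theta_des)^2 +
#' w3 (theta_dot+ - theta_dot_des)^2` over nonnegative activations, where
#' `(theta+, theta_dot+)` is a semi-implicit Euler one-step prediction of the
#' plant from `state` under activations `a` (muscle torque is linear in `a`
#' through the transforms `h`). The resulting nonnegative quadratic program
#' is solved exactly by a dense active-set method.
#'
#' @param model A [one_dof_model()].
#' @param state List with `theta` and `theta_dot`.
#' @param theta_des,theta_dot_des Desired state at the end of the step.
#' @param config An [fso_config()].
#' @param dt Prediction/control step, s.
#' @return Nonnegative activation vector.
#' @export
fso_step <- function(model, state, theta_des, theta_dot_des,
                     config = fso_config(), dt = 1e-3) {
  if (dt <= 0) stop("dt must be positive")
  m <- length(model$muscles)
  h <- h_vector(model, state$theta, state$theta_dot)
  I <- model$inertia(state$theta)
  tau0 <- model$gravity(state$theta) - model$damping * state$theta_dot
  p <- state$theta_dot + dt * tau0 / I
  q <- dt * h / I
  e2 <- state$theta + dt * p - theta_des
  e3 <- p - theta_dot_des
  Q <- diag(2 * config$w1, m) + 2 * (config$w2 * dt^2 + config$w3) * tcrossprod(q)
  cvec <- 2 * (config$w2 * dt * e2 + config$w3 * e3) * q
  qp_nonneg(Q, cvec)
}

#' Simulate forward-static-optimization tracking
#'
#' At every step the controller minimizes a weighted sum of squared muscular
#' effort and predicted tracking error,
#' `w1 sum(a^2) + w2 (theta+ - theta_des)^2 + w3 (theta_dot+ - theta_dot_des)^2`
#' over nonnegative activations, where `(theta+, theta_dot+)` is a
#' semi-implicit Euler one-step prediction of the plant (torque linear in the
#' activations through the transforms `h`). The resulting nonnegative
#' quadratic program is solved exactly by the dense active-set solver. On a
#' solver failure the previous activation vector is held and counted.
#'
#' @inheritParams simulate_pid
#' @param config An [fso_config()].
#' @return A `simulation_result`.
#' @export
simulate_fso <- function(model, trajectory, config = fso_config(), dt = 1e-3,
                         label = "fso") {
  times <- sim_times(trajectory$duration, dt)
  n <- length(times); m <- length(model$muscles)
  tr0 <- trajectory_eval(trajectory, 0)
  state <- list(theta = tr0$theta, theta_dot = tr0$theta_dot)
  theta <- numeric(n); theta_dot <- numeric(n); theta_des <- numeric(n)
  acts <- matrix(0, n, m); tau_dem <- numeric(n); tau_prod <- numeric(n)
  a_prev <- numeric(m)
  failures <- 0L
  for (k in seq_len(n)) {
    tr <- trajectory_eval(trajectory, times[k])
    trn <- trajectory_eval(trajectory, times[k] + dt)
    a <- tryCatch(fso_step(model, state, trn$theta, trn$theta_dot, config, dt),
                  error = function(err) NULL)
    if (is.null(a)) { failures <- failures + 1L; a <- a_prev } else a_prev <- a
    theta[k] <- state$theta; theta_dot[k] <- state$theta_dot
    theta_des[k] <- tr$theta; acts[k, ] <- a
    tau_dem[k] <- inverse_dynamics_torque(model, tr)
    tau_prod[k] <- net_torque(model, state$theta, state$theta_dot, a) +
      model$damping * state$theta_dot - model$gravity(state$theta)
    if (k < n) state <- plant_step(model, state, a, dt)
  }
  colnames(acts) <- model$cache$names
  new_simulation_result(label, times, theta, theta_dot, theta_des, acts,
                        tau_dem, tau_prod, solver_failures = failures)
}

#' Run the controller comparison experiment
#'
#' Simulates the same plant tracking the same reference trajectory under (i)
#' forward static optimization modulating every muscle individually (the
#' optimal baseline), (ii) PID driving the posture-dependent synergy table,
#' and optionally (iii) PID driving static NNMF synergies, and tabulates
#' effort and RMS tracking error per controller.
#'
#' @param model A [one_dof_model()].
#' @param trajectory A [trajectory_spec()].
#' @param table A `synergy_table` (default: built from the model's designated
#'   representatives).
#' @param static_synergies Optional scaled `static_synergies` for the NNMF
#'   arm; `NULL` skips it.
#' @param pid A [pid_config()]; `fso` an [fso_config()].
#' @param fso An [fso_config()].
#' @param dt Step size, s.
#' @return A `comparison_report`: list with per-controller
#'   `simulation_result`s and a `summary` data frame (controller, effort,
#'   rms_error).
#' @export
run_comparison <- function(model, trajectory, table = NULL,
                           static_synergies = NULL, pid = pid_config(),
                           fso = fso_config(), dt = 1e-3) {
  if (is.null(table)) table <- build_synergy_table(model)
  results <- list(
    fso = simulate_fso(model, trajectory, fso, dt, label = "fso"),
    pid_table = simulate_pid(model, table, trajectory, pid, dt,
                             label = "pid_table"))
  if (!is.null(static_synergies))
    results$pid_nnmf <- simulate_pid(model, static_synergies, trajectory, pid,
                                     dt, label = "pid_nnmf")
  summary <- data.frame(
    controller = names(results),
    effort = vapply(results, function(r) r$effort, numeric(1)),
    rms_error = vapply(results, function(r) r$rms_error, numeric(1)),
    solver_failures = vapply(results, function(r) r$solver_failures, integer(1)),
    row.names = NULL)
  structure(list(results = results, summary = summary,
                 model_name = model$name), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> model %s\n", x$model_name))
  print(x$summary)
  invisible(x)
}

#' Export a simulation result as CSV + JSON summary
#'
#' Writes one CSV row per timestep (time, desired and actual state, torques,
#' per-muscle activations) and a JSON summary (effort, RMS error).
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the controller label.
#' @return Paths of the files written, invisibly.
#' @export
write_simulation_result <- function(result, dir, prefix = result$controller) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(time = result$time, theta = result$theta,
                   theta_dot = result$theta_dot, theta_des = result$theta_des,
                   torque_demand = result$torque_demand,
                   torque_produced = result$torque_produced,
                   result$activations, check.names = FALSE)
  csv <- file.path(dir, paste0(prefix, "_timeseries.csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(controller = result$controller,
                            effort = result$effort,
                            rms_error = result$rms_error,
                            solver_failures = result$solver_failures,
                            duration = max(result$time)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Export a comparison report (summary CSV/JSON + per-run time series)
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_comparison <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "comparison_summary.csv")
  utils::write.csv(report$summary, paths, row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "comparison_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (r in report$results) paths <- c(paths, write_simulation_result(r, dir))
  invisible(paths)
}
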