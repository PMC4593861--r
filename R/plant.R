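#' Construct a one-degree-of-freedom musculoskeletal plant
#'
#' A plant is a single operational-space coordinate `theta` (elbow flexion
#' angle, crank/steering angle, ...) driven by a set of Hill-type muscles,
#' with effective inertia, optional gravity torque and viscous damping.
#'
#' @param muscles List of [muscle_params()] objects. The set must contain at
#'   least one muscle with positive and one with negative torque transform
#'   somewhere in the joint range (both torque directions actuated).
#' @param inertia Effective operational-space inertia: a positive number or a
#'   function of `theta` returning kg m^2.
#' @param theta_range Joint range `[min, max]`, rad. Motion is clipped at hard
#'   stops.
#' @param gravity_torque Gravity (or other posture-dependent tonic) torque: a
#'   number or a function of `theta` returning N m. Default 0 (horizontal
#'   plane convention).
#' @param damping Viscous damping coefficient, N m s/rad.
#' @param rep_pos,rep_neg Optional designated representative muscles (name or
#'   index) for the positive- and negative-torque synergies.
#' @param name Model label.
#' @return An object of class `one_dof_model`.
#' @export
one_dof_model <- function(muscles, inertia, theta_range,
                          gravity_torque = 0, damping = 0,
                          rep_pos = NULL, rep_neg = NULL, name = "model") {
  stopifnot(is.list(muscles), length(muscles) >= 1L)
  if (!all(vapply(muscles, inherits, logical(1), "muscle_params")))
    stop("muscles must be a list of muscle_params objects")
  stopifnot(length(theta_range) == 2L, theta_range[1] < theta_range[2])
  inertia_fn <- if (is.function(inertia)) inertia else function(theta) inertia
  gravity_fn <- if (is.function(gravity_torque)) gravity_torque
                else function(theta) rep(gravity_torque, length(theta))
  if (damping < 0) stop("damping must be nonnegative")
  model <- structure(
    list(muscles = muscles, inertia = inertia_fn, gravity = gravity_fn,
         damping = damping, theta_range = as.numeric(theta_range),
         rep_pos = rep_pos, rep_neg = rep_neg, name = name),
    class = "one_dof_model")
  model$cache <- build_model_cache(muscles)
  thetas <- seq(theta_range[1], theta_range[2], length.out = 25)
  if (any(inertia_fn(thetas) <= 0)) stop("inertia must be positive over range")
  hs <- vapply(thetas, function(th) h_vector(model, th), numeric(length(muscles)))
  if (!any(hs > 0) || !any(hs < 0))
    stop("model needs muscles acting in both torque directions")
  model
}

#' @export
print.one_dof_model <- function(x, ...) {
  cat(sprintf("<one_dof_model> %s: %d muscles, theta in [%.2f, %.2f] rad\n",
              x$name, length(x$muscles), x$theta_range[1], x$theta_range[2]))
  invisible(x)
}

# Pads per-muscle length polynomials into matrices for vectorised evaluation.
build_model_cache <- function(muscles) {
  m <- length(muscles)
  deg <- max(vapply(muscles, function(mu) length(mu$length_poly), integer(1)))
  P <- matrix(0, m, deg)
  for (i in seq_len(m)) {
    cf <- muscles[[i]]$length_poly
    P[i, seq_along(cf)] <- cf
  }
  D <- if (deg > 1L) P[, -1L, drop = FALSE] %*% diag(seq_len(deg - 1L), deg - 1L)
       else matrix(0, m, 1L)
  grab <- function(field) vapply(muscles, function(mu) as.numeric(mu[[field]]), numeric(1))
  list(P = P, D = D, deg = deg,
       F0max = grab("F0max"), cosp = cos(grab("pennation")),
       l_opt = grab("l_opt"), l_slack = grab("l_slack"),
       v_max = grab("v_max"), fl_width = grab("fl_width"),
       fv_shape = grab("fv_shape"), fv_ceiling = grab("fv_ceiling"),
       a_dep = vapply(muscles, function(mu) isTRUE(mu$fv_a_dependence), logical(1)),
       names = vapply(muscles, function(mu) mu$name, character(1)))
}

# Vectorised force-velocity multiplier with per-muscle constants.
fv_multiplier <- function(v_norm, a, shape, ceiling, a_dep) {
  v <- ifelse(a_dep, v_norm / (0.25 + 0.75 * a), v_norm)
  conc <- v <= 0
  vc <- pmax(v, -1)
  ifelse(conc, (1 + vc) / (1 - vc / shape),
         (1 + ceiling * v / shape) / (1 + v / shape))
}

# Per-muscle Hill-model quantities at a shared scalar state (vectorised over
# muscles). Returns fl, fv, moment arms, forces for given activation vector.
model_mechanics <- function(model, theta, theta_dot, a) {
  cc <- model$cache
  pw <- theta^(0:(cc$deg - 1L))
  l_mt <- as.vector(cc$P %*% pw)
  r <- -as.vector(cc$D %*% pw[seq_len(max(cc$deg - 1L, 1L))])
  l_norm <- (l_mt - cc$l_slack) / cc$l_opt
  if (any(l_norm <= 0)) stop("nonpositive normalised fibre length")
  v_norm <- (-r * theta_dot) / (cc$l_opt * cc$v_max)
  fl <- exp(-(l_norm - 1)^2 / cc$fl_width)
  fv <- fv_multiplier(v_norm, pmin(a, 1), cc$fv_shape, cc$fv_ceiling, cc$a_dep)
  list(r = r, fl = fl, fv = fv,
       force = a * cc$F0max * fl * fv * cc$cosp)
}

#' Torque transforms h of all muscles in a model
#'
#' Evaluates [h_analytic()] for every muscle at a shared state, vectorised.
#'
#' @param model A [one_dof_model()].
#' @param theta Joint angle, rad (scalar).
#' @param theta_dot Joint angular velocity, rad/s.
#' @param a_ref Reference activation for the (optional) activation dependence
#'   of the force-velocity curve.
#' @return Numeric vector of torque-per-unit-activation, N m, one per muscle.
#' @export
h_vector <- function(model, theta, theta_dot = 0, a_ref = 0.5) {
  check_theta_range(theta, model$theta_range)
  mech <- model_mechanics(model, theta, theta_dot, rep(a_ref, length(model$muscles)))
  stats::setNames(model$cache$F0max * mech$fl * mech$fv * model$cache$cosp * mech$r,
                  model$cache$names)
}

#' Net operational-space torque
#'
#' Sum of muscle torques `F_i r_i(theta)` plus gravity minus viscous damping.
#'
#' @inheritParams h_vector
#' @param activations Nonnegative activation vector, one entry per muscle.
#' @return Net torque, N m.
#' @export
net_torque <- function(model, theta, theta_dot, activations) {
  m <- length(model$muscles)
  if (length(activations) != m)
    stop("activations length must equal the number of muscles")
  if (any(activations < 0)) stop("activations must be nonnegative")
  check_theta_range(theta, model$theta_range)
  mech <- model_mechanics(model, theta, theta_dot, activations)
  sum(mech$force * mech$r) + model$gravity(theta) - model$damping * theta_dot
}

model_acceleration <- function(model, theta, theta_dot, activations) {
  net_torque(model, theta, theta_dot, activations) / model$inertia(theta)
}

#' Advance the plant by one fixed time step
#'
#' Classical fourth-order Runge-Kutta update of `(theta, theta_dot)` with
#' activations held constant over the step. The angle is clipped to the joint
#' range; velocity is zeroed at the hard stops.
#'
#' @param model A [one_dof_model()].
#' @param state List with elements `theta` and `theta_dot`.
#' @param activations Nonnegative activation vector.
#' @param dt Step size, s (> 0).
#' @return Updated state list.
#' @export
plant_step <- function(model, state, activations, dt) {
  if (dt <= 0) stop("dt must be positive")
  th <- state$theta; om <- state$theta_dot
  if (!is.finite(th) || !is.finite(om)) stop("non-finite plant state")
  rng <- model$theta_range
  # intermediate stages may poke past a hard stop; evaluate them at the stop
  acc <- function(th, om)
    model_acceleration(model, min(max(th, rng[1]), rng[2]), om, activations)
  k1o <- acc(th, om);                         k1t <- om
  k2o <- acc(th + dt/2 * k1t, om + dt/2 * k1o); k2t <- om + dt/2 * k1o
  k3o <- acc(th + dt/2 * k2t, om + dt/2 * k2o); k3t <- om + dt/2 * k2o
  k4o <- acc(th + dt * k3t, om + dt * k3o);     k4t <- om + dt * k3o
  th_new <- th + dt/6 * (k1t + 2*k2t + 2*k3t + k4t)
  om_new <- om + dt/6 * (k1o + 2*k2o + 2*k3o + k4o)
  if (th_new <= rng[1]) { th_new <- rng[1]; om_new <- 0 }
  if (th_new >= rng[2]) { th_new <- rng[2]; om_new <- 0 }
  if (!is.finite(th_new) || !is.finite(om_new)) stop("non-finite plant state")
  list(theta = th_new, theta_dot = om_new)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Seven-muscle elbow flexion/extension fixture
#'
#' A planar one-DoF forearm model actuated by brachioradialis, brachialis, the
#' two biceps brachii heads (flexors: positive moment arm) and the three
#' triceps brachii heads (extensors). Muscle strengths, fibre lengths and
#' pennation angles follow standard published upper-limb models; moment-arm
#' profiles are smooth quadratics peaking near mid-flexion. These values are a
#' documented synthetic stand-in, not a reproduction of any specific dataset.
#' Gravity defaults to zero (horizontal-plane convention).
#'
#' @param fv_a_dependence Logical; propagate an activation-dependent
#'   force-velocity curve to every muscle (default off).
#' @return A [one_dof_model()] with `rep_pos = "biceps_long"` and
#'   `rep_neg = "triceps_long"`.
#' @export
forearm_model <- function(fv_a_dependence = FALSE) {
  rng <- c(0, 2.6)
  # name, F0max, l_opt, l_slack, pennation, moment-arm quadratic (p0, p1, p2)
  spec <- list(
    list("brachioradialis", 262, 0.173, 0.133, 0.00, c(0.035, 0.030, -0.0115)),
    list("brachialis",      987, 0.086, 0.054, 0.00, c(0.018, 0.010, -0.0040)),
    list("biceps_long",     624, 0.116, 0.272, 0.00, c(0.025, 0.020, -0.0077)),
    list("biceps_short",    436, 0.132, 0.192, 0.00, c(0.023, 0.022, -0.0080)),
    list("triceps_long",    799, 0.134, 0.143, 0.21, c(-0.021, -0.004, 0.0015)),
    list("triceps_lateral", 624, 0.114, 0.098, 0.16, c(-0.019, -0.005, 0.0019)),
    list("triceps_medial",  624, 0.114, 0.091, 0.16, c(-0.018, -0.006, 0.0023)))
  mid <- mean(rng)
  muscles <- lapply(spec, function(s) {
    p <- s[[6]]
    # length poly integrates -r; constant set so l_norm = 1 at mid-range
    c123 <- c(-p[1], -p[2] / 2, -p[3] / 3)
    c0 <- s[[4]] + s[[3]] - sum(c123 * mid^(1:3))
    muscle_params(name = s[[1]], F0max = s[[2]], l_opt = s[[3]],
                  l_slack = s[[4]], pennation = s[[5]],
                  length_poly = c(c0, c123), theta_range = rng,
                  fv_a_dependence = fv_a_dependence)
  })
  one_dof_model(muscles, inertia = 0.072, theta_range = rng,
                gravity_torque = 0, damping = 0.05,
                rep_pos = "biceps_long", rep_neg = "triceps_long",
                name = "forearm")
}

#' Generate a planar crank model with a sign-switching muscle
#'
#' Builds a seeded-random one-DoF crank (steering) model that reproduces the
#' qualitative structure of multi-joint driving models: most muscles keep a
#' fixed rotation direction, but at least one changes function (its torque
#' transform h crosses zero) at some crank angle, so it cannot serve as a
#' synergy representative. Muscle 1 is a guaranteed counter-clockwise
#' (positive-h) rotator, muscle 2 a guaranteed clockwise rotator, muscle 3 the
#' designated sign-switcher; remaining muscles are unconstrained random draws.
#'
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param n_muscles Number of muscles (>= 4).
#' @param include_gravity Logical; add a small tonic posture-dependent torque.
#' @param max_retries Bounded retries for constraint-satisfying generation.
#' @return A [one_dof_model()] with fields `rep_pos = 1`, `rep_neg = 2` and
#'   attribute `switch_index = 3`.
#' @export
make_crank_model <- function(seed, n_muscles = 6, include_gravity = FALSE,
                             max_retries = 100) {
  if (n_muscles < 4) stop("n_muscles must be at least 4")
  rng <- c(-pi / 2, pi / 2)
  thetas <- seq(rng[1], rng[2], length.out = 101)
  draw_muscle <- function(i, kind) {
    for (try in seq_len(max_retries)) {
      p <- switch(kind,
        pos = c(stats::runif(1, 0.02, 0.04), stats::runif(1, -0.01, 0.01),
                stats::runif(1, -0.006, 0.006)),
        neg = -c(stats::runif(1, 0.02, 0.04), stats::runif(1, -0.01, 0.01),
                 stats::runif(1, -0.006, 0.006)),
        switch = {
          th0 <- stats::runif(1, -0.6, 0.6)
          k <- sample(c(-1, 1), 1) * stats::runif(1, 0.02, 0.05)
          c(-k * th0, k, 0)
        },
        free = c(stats::runif(1, -0.03, 0.03), stats::runif(1, -0.02, 0.02),
                 stats::runif(1, -0.008, 0.008)))
      r <- p[1] + p[2] * thetas + p[3] * thetas^2
      ok <- switch(kind,
        pos = min(r) > 0.004,
        neg = max(r) < -0.004,
        switch = min(r) < -0.004 && max(r) > 0.004,
        free = max(abs(r)) > 0.004)
      if (!ok) next
      l_opt <- stats::runif(1, 0.10, 0.15)
      l_slack <- stats::runif(1, 0.05, 0.20)
      c123 <- c(-p[1], -p[2] / 2, -p[3] / 3)
      c0 <- l_slack + l_opt - sum(c123 * 0^(1:3))  # l_norm = 1 at theta = 0
      l_norm <- (c0 + c123[1] * thetas + c123[2] * thetas^2 +
                   c123[3] * thetas^3 - l_slack) / l_opt
      if (min(l_norm) < 0.55 || max(l_norm) > 1.45) next
      return(muscle_params(name = sprintf("m%02d_%s", i, kind),
                           F0max = stats::runif(1, 300, 900),
                           l_opt = l_opt, l_slack = l_slack,
                           length_poly = c(c0, c123), theta_range = rng))
    }
    stop("crank muscle generation failed after bounded retries")
  }
  with_seed(seed, {
    kinds <- c("pos", "neg", "switch", rep("free", n_muscles - 3L))
    muscles <- lapply(seq_len(n_muscles), function(i) draw_muscle(i, kinds[i]))
    gfun <- if (include_gravity) {
      amp <- stats::runif(1, 0.2, 0.8)
      function(theta) -amp * sin(theta)
    } else 0
    model <- one_dof_model(muscles, inertia = 0.1, theta_range = rng,
                           gravity_torque = gfun, damping = 0.1,
                           rep_pos = 1L, rep_neg = 2L, name = "crank")
    attr(model, "switch_index") <- 3L
    model
  })
}

#' Resolve a muscle reference (name or index) to an index
#'
#' @param model A [one_dof_model()].
#' @param ref Muscle name or integer index.
#' @return Integer index into `model$muscles`.
#' @export
muscle_index <- function(model, ref) {
  if (is.null(ref)) stop("muscle reference is NULL")
  if (is.numeric(ref)) {
    i <- as.integer(ref)
    if (i < 1L || i > length(model$muscles)) stop("muscle index out of range")
    return(i)
  }
  i <- match(ref, model$cache$names)
  if (is.na(i)) stop(sprintf("unknown muscle '%s'", ref))
  i
}
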