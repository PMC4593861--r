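# Shared fixtures, built in code. The forearm/crank constructors are fast, so
# each helper returns a fresh object (no cross-test state).

fixture_forearm <- function(...) forearm_model(...)

fixture_crank <- function(seed = 42, ...) make_crank_model(seed, ...)

# A two-muscle toy plant with constant moment arms (+-r0) and flat
# force-length curves near mid-range; handy for closed-form checks.
fixture_toy <- function(inertia = 0.1, damping = 0, gravity = 0, r0 = 0.03) {
  rng <- c(-1, 1)
  mk <- function(name, sgn) {
    # linear length poly -> constant moment arm sgn * r0
    muscle_params(name = name, F0max = 100, l_opt = 0.1, l_slack = 0.2,
                  length_poly = c(0.3, -sgn * r0), theta_range = rng)
  }
  one_dof_model(list(mk("flex", +1), mk("ext", -1)), inertia = inertia,
                theta_range = rng, gravity_torque = gravity, damping = damping,
                rep_pos = "flex", rep_neg = "ext", name = "toy")
}

# Seeded random force-sharing problems with mixed-sign h entries,
# |h| >= 0.1, h ~ U(-5, 5), T ~ U(-10, 10).
random_sharing_problems <- function(n, seed) {
  with_seed_test(seed, lapply(seq_len(n), function(i) {
    repeat {
      m <- sample(3:8, 1)
      h <- stats::runif(m, -5, 5)
      h <- h[abs(h) >= 0.1]
      if (length(h) >= 2 && any(h > 0) && any(h < 0)) break
    }
    list(h = h, T_demand = stats::runif(1, -10, 10))
  }))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Strip closures (inertia/gravity functions) for determinism comparisons.
comparable_model <- function(model) {
  model[c("muscles", "damping", "theta_range", "rep_pos", "rep_neg", "name")]
}
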