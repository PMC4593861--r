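#' Construct a Hill-type muscle parameter set
#'
#' Bundles the constants of a rigid-tendon Hill muscle acting about a single
#' joint. Musculotendon length is a polynomial in the joint angle `theta`
#' (coefficients in increasing degree, metres), so the moment arm is minus its
#' derivative; this guarantees that moment arm and length excursion are
#' mutually consistent.
#'
#' @param name Muscle label.
#' @param F0max Maximum isometric force, N. Must be positive.
#' @param length_poly Numeric vector of polynomial coefficients (increasing
#'   degree) giving musculotendon length in metres as a function of joint
#'   angle in radians.
#' @param l_opt Optimal fibre length, m.
#' @param l_slack Tendon slack length, m (tendon is rigid: fibre length is
#'   musculotendon length minus `l_slack`).
#' @param pennation Pennation angle, rad, in `[0, pi/2)`.
#' @param v_max Maximum shortening velocity, optimal fibre lengths per second.
#' @param fl_width Width `gamma` of the Gaussian active force-length curve.
#' @param fv_shape Curvature constant of the force-velocity curve.
#' @param fv_ceiling Asymptotic eccentric force multiplier (> 1).
#' @param fv_a_dependence Logical; if `TRUE` the force-velocity curve's
#'   effective maximum velocity is scaled by activation (Thelen-style
#'   `0.25 + 0.75 a`). Off by default: the activation-to-torque transform is
#'   nearly flat in activation, so the dependence is neglected.
#' @param theta_range Optional joint range `[min, max]` in radians; when
#'   present, kinematic queries outside it raise an error.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(name, F0max, length_poly, l_opt, l_slack,
                          pennation = 0, v_max = 10,
                          fl_width = 0.45, fv_shape = 0.25, fv_ceiling = 1.4,
                          fv_a_dependence = FALSE, theta_range = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(F0max) || F0max <= 0) stop("F0max must be positive")
  if (!is.numeric(l_opt) || l_opt <= 0) stop("l_opt must be positive")
  if (!is.numeric(v_max) || v_max <= 0) stop("v_max must be positive")
  if (pennation < 0 || pennation >= pi / 2)
    stop("pennation must be in [0, pi/2)")
  if (!is.numeric(length_poly) || length(length_poly) < 1L)
    stop("length_poly must be a numeric coefficient vector")
  if (fl_width <= 0) stop("fl_width must be positive")
  if (fv_ceiling <= 1) stop("fv_ceiling must exceed 1")
  structure(
    list(name = name, F0max = as.numeric(F0max),
         length_poly = as.numeric(length_poly), l_opt = as.numeric(l_opt),
         l_slack = as.numeric(l_slack), pennation = as.numeric(pennation),
         v_max = as.numeric(v_max), fl_width = as.numeric(fl_width),
         fv_shape = as.numeric(fv_shape), fv_ceiling = as.numeric(fv_ceiling),
         fv_a_dependence = isTRUE(fv_a_dependence),
         theta_range = if (!is.null(theta_range)) as.numeric(theta_range)),
    class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params> %s: F0max = %.1f N, l_opt = %.3f m, pennation = %.3f rad\n",
              x$name, x$F0max, x$l_opt, x$pennation))
  invisible(x)
}

polyval <- function(coef, x) {
  # Horner evaluation, coefficients in increasing degree
  out <- rep(0, length(x))
  for (c_k in rev(coef)) out <- out * x + c_k
  out
}

polyderiv <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

check_theta_range <- function(theta, range, what = "theta") {
  if (!is.null(range) &&
      (any(theta < range[1] - 1e-12) || any(theta > range[2] + 1e-12)))
    stop(sprintf("%s outside configured joint range [%g, %g]",
                 what, range[1], range[2]))
  invisible(TRUE)
}

#' Musculotendon length at a posture
#'
#' @param muscle A [muscle_params()] object.
#' @param theta Joint angle, rad.
#' @return Length in metres.
#' @export
musculotendon_length <- function(muscle, theta) {
  check_theta_range(theta, muscle$theta_range)
  polyval(muscle$length_poly, theta)
}

#' Moment arm about the joint
#'
#' The moment arm is minus the derivative of musculotendon length with respect
#' to the joint angle: positive for muscles that shorten as `theta` increases
#' (flexors), negative for extensors.
#'
#' @inheritParams musculotendon_length
#' @return Moment arm in metres (signed).
#' @export
moment_arm <- function(muscle, theta) {
  check_theta_range(theta, muscle$theta_range)
  -polyval(polyderiv(muscle$length_poly), theta)
}

#' Active force-length multiplier
#'
#' Gaussian curve `exp(-(l_norm - 1)^2 / width)`, maximal (1) at the optimal
#' fibre length.
#'
#' @param l_norm Fibre length normalised by optimal fibre length; must be
#'   positive.
#' @param width Gaussian width `gamma`.
#' @return Dimensionless multiplier in (0, 1].
#' @export
force_length <- function(l_norm, width = 0.45) {
  if (any(l_norm <= 0)) stop("l_norm must be positive")
  exp(-(l_norm - 1)^2 / width)
}

#' Force-velocity multiplier
#'
#' Hill-type hyperbolic curve. `v_norm` is fibre velocity normalised by the
#' maximum shortening velocity, negative when shortening: the multiplier is 1
#' at zero velocity, falls to 0 at `v_norm = -1`, and rises above 1 for
#' lengthening, saturating at `ceiling`. When `a_dependence` is on, the
#' effective maximum shortening velocity scales with activation as
#' `0.25 + 0.75 a`.
#'
#' @param v_norm Normalised fibre velocity (negative = shortening).
#' @param a Activation in `[0, 1]`; only used when `a_dependence = TRUE`.
#' @param shape Curvature constant of the shortening branch.
#' @param ceiling Eccentric saturation level (> 1).
#' @param a_dependence Logical switch for the activation scaling.
#' @return Dimensionless multiplier, `>= 0`.
#' @export
force_velocity <- function(v_norm, a = 0.5, shape = 0.25, ceiling = 1.4,
                           a_dependence = FALSE) {
  if (any(a < 0) || any(a > 1)) stop("activation must be in [0, 1]")
  if (a_dependence) v_norm <- v_norm / (0.25 + 0.75 * a)
  out <- numeric(length(v_norm))
  conc <- v_norm <= 0
  vc <- pmax(v_norm[conc], -1)
  out[conc] <- (1 + vc) / (1 - vc / shape)
  ve <- v_norm[!conc]
  # Katz-type eccentric branch: 1 at v = 0, asymptote at `ceiling`
  out[!conc] <- (1 + ceiling * ve / shape) / (1 + ve / shape)
  out
}

# Normalised fibre kinematics under the rigid-tendon assumption.
fiber_kinematics <- function(muscle, theta, theta_dot) {
  l_mt <- musculotendon_length(muscle, theta)
  l_fib <- l_mt - muscle$l_slack
  l_norm <- l_fib / muscle$l_opt
  # d(l_fib)/dt = dl_mt/dtheta * theta_dot = -r(theta) * theta_dot
  v_fib <- -moment_arm(muscle, theta) * theta_dot
  v_norm <- v_fib / (muscle$l_opt * muscle$v_max)
  list(l_norm = l_norm, v_norm = v_norm)
}

#' Hill-model muscle force
#'
#' `F = a * F0max * f_l(theta) * f_v(theta_dot) * cos(pennation)` with fibre
#' kinematics derived from the muscle's length polynomial (rigid tendon).
#'
#' @inheritParams musculotendon_length
#' @param theta_dot Joint angular velocity, rad/s.
#' @param a Activation, `>= 0`.
#' @return Tendon-direction force, N.
#' @export
muscle_force <- function(muscle, theta, theta_dot = 0, a = 0) {
  if (any(a < 0)) stop("activation must be nonnegative")
  kin <- fiber_kinematics(muscle, theta, theta_dot)
  fl <- force_length(kin$l_norm, muscle$fl_width)
  fv <- force_velocity(kin$v_norm, a = min(a, 1), shape = muscle$fv_shape,
                       ceiling = muscle$fv_ceiling,
                       a_dependence = muscle$fv_a_dependence)
  a * muscle$F0max * fl * fv * cos(muscle$pennation)
}

#' Activation-to-torque transform h of one muscle
#'
#' The gain that maps a muscle's activation to the torque it produces in the
#' one-dimensional operational space:
#' `h = F0max * f_l(theta) * f_v(theta_dot) * cos(pennation) * r(theta)`.
#' Its sign follows the moment arm (positive for flexors). Any activation
#' dependence of the force-velocity curve is frozen at `a_ref` (the transform
#' is nearly flat in activation, so a mid-range reference loses little).
#'
#' @inheritParams muscle_force
#' @param a_ref Reference activation at which the (optional) activation
#'   dependence of the force-velocity curve is evaluated.
#' @return Torque per unit activation, N m.
#' @export
h_analytic <- function(muscle, theta, theta_dot = 0, a_ref = 0.5) {
  kin <- fiber_kinematics(muscle, theta, theta_dot)
  fl <- force_length(kin$l_norm, muscle$fl_width)
  fv <- force_velocity(kin$v_norm, a = a_ref, shape = muscle$fv_shape,
                       ceiling = muscle$fv_ceiling,
                       a_dependence = muscle$fv_a_dependence)
  muscle$F0max * fl * fv * cos(muscle$pennation) * moment_arm(muscle, theta)
}
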