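#' Construct a force-sharing problem
#'
#' The effort-minimizing force-sharing problem: find nonnegative activations
#' `a` minimizing `sum(a^2)` subject to `sum(a * h) = T`, where `h` holds each
#' muscle's activation-to-torque transform and `T` is the demanded
#' operational-space torque.
#'
#' @param h Numeric vector of torque transforms, N m per unit activation.
#'   For a well-posed bidirectional joint it should contain both signs.
#' @param T_demand Demanded torque, N m.
#' @return An object of class `sharing_problem`.
#' @export
sharing_problem <- function(h, T_demand) {
  if (!all(is.finite(h))) stop("h must be finite")
  if (!is.finite(T_demand)) stop("T_demand must be finite")
  nm <- names(h)
  h <- as.numeric(h); names(h) <- nm
  structure(list(h = h, T_demand = as.numeric(T_demand)),
            class = "sharing_problem")
}

resolve_problem <- function(problem, T_demand) {
  if (inherits(problem, "sharing_problem")) problem
  else sharing_problem(problem, T_demand)
}

#' Closed-form optimal activations
#'
#' Muscles whose transform sign matches the demanded torque (the agonist set)
#' activate in fixed mutual ratios `a_i = h_i * T / sum_{agonists}(h_j^2)`;
#' all antagonists are exactly zero. This is the KKT solution of the
#' quadratic force-sharing problem: the torque constraint holds exactly, every
#' activation is nonnegative, and `sum(a^2)` is minimal. Activations above 1
#' indicate the demand is outside the sub-maximal regime; a warning is issued
#' but no upper bound is imposed.
#'
#' @param problem A [sharing_problem()], or a numeric `h` vector (then supply
#'   `T_demand`).
#' @param T_demand Demanded torque when `problem` is a bare `h` vector.
#' @return Nonnegative activation vector of the same length as `h`.
#' @export
optimal_activations <- function(problem, T_demand = NULL) {
  pr <- resolve_problem(problem, T_demand)
  h <- pr$h; T_d <- pr$T_demand
  a <- numeric(length(h)); names(a) <- names(h)
  if (T_d == 0) return(a)
  agonist <- sign(h) == sign(T_d)
  if (!any(agonist))
    stop("infeasible: no muscle can produce torque of the demanded sign")
  a[agonist] <- h[agonist] * T_d / sum(h[agonist]^2)
  if (any(a > 1))
    warning("optimal activation exceeds 1: demand outside the sub-maximal regime")
  a
}

# Generic primal active-set solver for min 1/2 a'Qa + c'a  s.t.  a >= 0,
# optionally with one equality constraint  h'a = T.  Solves the KKT linear
# system on the current free set with dense linear algebra; adds/drops bounds
# until primal and dual feasibility hold.
qp_nonneg <- function(Q, c, h = NULL, T_eq = NULL, tol = 1e-9, max_iter = NULL) {
  n <- length(c)
  if (is.null(max_iter)) max_iter <- 4L * n + 20L
  free <- rep(TRUE, n)
  a <- numeric(n)
  lambda <- 0
  for (iter in seq_len(max_iter)) {
    idx <- which(free)
    if (length(idx) == 0L) {
      if (!is.null(h) && abs(T_eq) > tol) stop("QP oracle: infeasible working set")
      a <- numeric(n)
    } else if (is.null(h)) {
      sol <- solve(Q[idx, idx, drop = FALSE], -c[idx])
      a <- numeric(n); a[idx] <- sol
    } else {
      k <- length(idx)
      K <- rbind(cbind(Q[idx, idx, drop = FALSE], h[idx]),
                 c(h[idx], 0))
      rhs <- c(-c[idx], T_eq)
      sol <- tryCatch(solve(K, rhs), error = function(e)
        stop("QP oracle: singular KKT system"))
      a <- numeric(n); a[idx] <- sol[seq_len(k)]
      # stationarity reads Q a - lambda h = -c; the system solves for -lambda
      lambda <- -sol[k + 1L]
    }
    if (any(a < -tol)) {
      drop_i <- which.min(a)
      free[drop_i] <- FALSE
      next
    }
    a[a < 0] <- 0
    # dual feasibility of clamped variables: reduced gradient must be >= 0
    grad <- as.vector(Q %*% a) + c
    if (!is.null(h)) grad <- grad - lambda * h
    clamped <- which(!free)
    if (length(clamped) && any(grad[clamped] < -tol)) {
      add_i <- clamped[which.min(grad[clamped])]
      free[add_i] <- TRUE
      next
    }
    return(a)
  }
  stop("QP oracle failed to converge")
}

#' Numerical force-sharing oracle
#'
#' Solves the same constrained quadratic program as [optimal_activations()]
#' with a generic dense active-set method (KKT linear systems, bound
#' add/drop), independent of the closed-form agonist/antagonist argument.
#' Intended as a verification oracle.
#'
#' @inheritParams optimal_activations
#' @param tol Feasibility/duality tolerance.
#' @return Nonnegative activation vector satisfying the torque constraint to
#'   numerical precision.
#' @export
qp_oracle <- function(problem, T_demand = NULL, tol = 1e-9) {
  pr <- resolve_problem(problem, T_demand)
  h <- pr$h; T_d <- pr$T_demand
  if (T_d == 0) return(stats::setNames(numeric(length(h)), names(h)))
  if (T_d > 0 && !any(h > 0)) stop("infeasible: demanded torque unattainable")
  if (T_d < 0 && !any(h < 0)) stop("infeasible: demanded torque unattainable")
  stats::setNames(qp_nonneg(Q = diag(2, length(h)), c = numeric(length(h)),
                            h = unname(h), T_eq = T_d, tol = tol), names(h))
}
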