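#' Probe a muscle's torque transform through the plant
#'
#' Numerical counterpart of [h_analytic()] for models whose mechanics are only
#' available through simulation: activate muscle `i` alone at posture `theta`
#' (zero velocity), measure the operational-space torque with gravity and
#' damping subtracted, and divide by the probe activation.
#'
#' @param model A [one_dof_model()].
#' @param muscle Muscle name or index.
#' @param theta Probe posture, rad.
#' @param a_probe Probe activation in (0, 1].
#' @return Torque per unit activation, N m.
#' @export
probe_h <- function(model, muscle, theta, a_probe = 0.5) {
  if (a_probe <= 0 || a_probe > 1) stop("a_probe must be in (0, 1]")
  check_theta_range(theta, model$theta_range)
  i <- muscle_index(model, muscle)
  a <- numeric(length(model$muscles)); a[i] <- a_probe
  tau <- net_torque(model, theta, 0, a) - net_torque(model, theta, 0, numeric(length(a)))
  tau / a_probe
}

#' Check candidate synergy representative muscles
#'
#' A representative must keep a fixed torque direction over the whole
#' workspace: the positive representative's transform `h` must be strictly
#' positive and the negative representative's strictly negative at every grid
#' posture. Muscles that change function with posture (h crosses zero) cannot
#' represent a synergy. Also reports sign constancy for every muscle.
#'
#' @param model A [one_dof_model()].
#' @param theta_grid Strictly increasing posture grid, rad (non-empty).
#' @param rep_pos,rep_neg Candidate representatives (name or index).
#' @return Invisibly, a list with per-muscle sign summary (`always_pos`,
#'   `always_neg`, `switches`) and `valid = TRUE`. Invalid candidates raise an
#'   `invalid_representative` error naming the posture of failure.
#' @export
validate_representatives <- function(model, theta_grid, rep_pos, rep_neg) {
  if (length(theta_grid) == 0L) stop("theta_grid must be non-empty")
  if (is.unsorted(theta_grid, strictly = TRUE))
    stop("theta_grid must be strictly increasing")
  ip <- muscle_index(model, rep_pos); ineg <- muscle_index(model, rep_neg)
  H <- vapply(theta_grid, function(th) h_vector(model, th),
              numeric(length(model$muscles)))  # muscles x grid
  fail <- function(which_rep, i, cond) {
    bad <- which(cond)[1]
    stop(structure(class = c("invalid_representative", "error", "condition"),
      list(message = sprintf(
        "invalid %s representative '%s': h = %.4g at theta = %.4f rad",
        which_rep, model$cache$names[i], H[i, bad], theta_grid[bad]),
        call = sys.call(-1))))
  }
  if (any(H[ip, ] <= 0)) fail("positive", ip, H[ip, ] <= 0)
  if (any(H[ineg, ] >= 0)) fail("negative", ineg, H[ineg, ] >= 0)
  summary <- data.frame(
    muscle = model$cache$names,
    always_pos = apply(H > 0, 1, all),
    always_neg = apply(H < 0, 1, all))
  summary$switches <- !summary$always_pos & !summary$always_neg
  invisible(list(valid = TRUE, summary = summary, rep_pos = ip, rep_neg = ineg))
}

#' Build a posture-dependent synergy-ratio table
#'
#' For a one-dimensional operational space, two synergies suffice: one for
#' positive and one for negative torque. At every grid posture the ratio of
#' muscle `i`'s optimal activation to the representative's is `h_i / h_rep`,
#' clamped at zero when the sign disagrees (antagonists are silent in the
#' optimum). Velocity dependence of `h` is weak and off by default; when
#' enabled the table is built on a `theta x theta_dot` grid.
#'
#' @param model A [one_dof_model()].
#' @param theta_grid Posture grid; default 101 uniform points over the model's
#'   joint range.
#' @param rep_pos,rep_neg Representative muscles (default: the model's
#'   designated ones). Must pass [validate_representatives()].
#' @param use_theta_dot Logical; include a velocity axis.
#' @param theta_dot_grid Velocity grid, rad/s (only when `use_theta_dot`).
#' @param a_probe Activation at which `h` is evaluated (frozen activation
#'   dependence).
#' @param method `"analytic"` uses [h_vector()]; `"probe"` measures `h`
#'   through [probe_h()] (torque-probe route for plants without analytic
#'   muscle paths).
#' @return An object of class `synergy_table` with matrices `S_pos`, `S_neg`
#'   (grid points x muscles, or a 3-d array when velocity-dependent).
#' @export
build_synergy_table <- function(model, theta_grid = NULL,
                                rep_pos = model$rep_pos, rep_neg = model$rep_neg,
                                use_theta_dot = FALSE, theta_dot_grid = NULL,
                                a_probe = 0.5, method = c("analytic", "probe")) {
  method <- match.arg(method)
  if (is.null(theta_grid))
    theta_grid <- seq(model$theta_range[1], model$theta_range[2], length.out = 101)
  val <- validate_representatives(model, theta_grid, rep_pos, rep_neg)
  ip <- val$rep_pos; ineg <- val$rep_neg
  m <- length(model$muscles)
  h_at <- function(th, thd) {
    if (method == "analytic") h_vector(model, th, thd, a_ref = a_probe)
    else vapply(seq_len(m), function(i) probe_h(model, i, th, a_probe), numeric(1))
  }
  ratios <- function(h) {
    if (h[ip] <= 0 || h[ineg] >= 0) stop("degenerate representative: h of wrong sign")
    list(pos = pmax(0, h / h[ip]), neg = pmax(0, h / h[ineg]))
  }
  if (!use_theta_dot) {
    S_pos <- matrix(0, length(theta_grid), m)
    S_neg <- matrix(0, length(theta_grid), m)
    for (k in seq_along(theta_grid)) {
      rr <- ratios(h_at(theta_grid[k], 0))
      S_pos[k, ] <- rr$pos; S_neg[k, ] <- rr$neg
    }
    theta_dot_grid <- NULL
  } else {
    if (is.null(theta_dot_grid)) theta_dot_grid <- seq(-3, 3, length.out = 13)
    S_pos <- array(0, c(length(theta_grid), length(theta_dot_grid), m))
    S_neg <- array(0, c(length(theta_grid), length(theta_dot_grid), m))
    for (k in seq_along(theta_grid)) for (j in seq_along(theta_dot_grid)) {
      rr <- ratios(h_at(theta_grid[k], theta_dot_grid[j]))
      S_pos[k, j, ] <- rr$pos; S_neg[k, j, ] <- rr$neg
    }
  }
  colnames_safe <- model$cache$names
  structure(list(theta_grid = theta_grid, theta_dot_grid = theta_dot_grid,
                 S_pos = S_pos, S_neg = S_neg,
                 rep_pos = ip, rep_neg = ineg,
                 muscle_names = colnames_safe, model_name = model$name),
            class = "synergy_table")
}

#' @export
print.synergy_table <- function(x, ...) {
  cat(sprintf("<synergy_table> %d muscles on %d theta points%s; rep+ = %s, rep- = %s\n",
              length(x$muscle_names), length(x$theta_grid),
              if (is.null(x$theta_dot_grid)) "" else
                sprintf(" x %d theta_dot points", length(x$theta_dot_grid)),
              x$muscle_names[x$rep_pos], x$muscle_names[x$rep_neg]))
  invisible(x)
}

interp_weights <- function(grid, x) {
  n <- length(grid)
  if (x < grid[1] - 1e-9 || x > grid[n] + 1e-9) stop("query outside table span")
  k <- findInterval(x, grid, rightmost.closed = TRUE)
  k <- min(max(k, 1L), n - 1L)
  w <- (x - grid[k]) / (grid[k + 1L] - grid[k])
  list(k = k, w = min(max(w, 0), 1))
}

# Interpolated synergy ratio columns at (theta, theta_dot).
table_columns <- function(table, theta, theta_dot = 0) {
  it <- interp_weights(table$theta_grid, theta)
  if (is.null(table$theta_dot_grid)) {
    pos <- (1 - it$w) * table$S_pos[it$k, ] + it$w * table$S_pos[it$k + 1L, ]
    neg <- (1 - it$w) * table$S_neg[it$k, ] + it$w * table$S_neg[it$k + 1L, ]
  } else {
    iv <- interp_weights(table$theta_dot_grid, theta_dot)
    bil <- function(S) {
      (1 - it$w) * ((1 - iv$w) * S[it$k, iv$k, ] + iv$w * S[it$k, iv$k + 1L, ]) +
        it$w * ((1 - iv$w) * S[it$k + 1L, iv$k, ] + iv$w * S[it$k + 1L, iv$k + 1L, ])
    }
    pos <- bil(table$S_pos); neg <- bil(table$S_neg)
  }
  list(pos = pos, neg = neg)
}

#' Reconstruct all muscle activations from two representative activations
#'
#' `a_i = a_pos * S_pos_i(theta) + a_neg * S_neg_i(theta)` with linear (or
#' bilinear) interpolation between grid points. The two scalars are the
#' activations of the representative muscles of the positive- and
#' negative-torque synergies.
#'
#' @param table A [build_synergy_table()] result.
#' @param a_pos,a_neg Nonnegative representative activations.
#' @param theta Query posture, rad (inside the table span).
#' @param theta_dot Query velocity (only for velocity-dependent tables).
#' @return Nonnegative activation vector, one entry per muscle.
#' @export
reconstruct_activations <- function(table, a_pos, a_neg, theta, theta_dot = 0) {
  if (a_pos < 0 || a_neg < 0) stop("representative activations must be nonnegative")
  cols <- table_columns(table, theta, theta_dot)
  stats::setNames(a_pos * cols$pos + a_neg * cols$neg, table$muscle_names)
}

#' Serialize a synergy table to JSON
#'
#' @param table A `synergy_table`.
#' @param path Output file path.
#' @export
write_synergy_table <- function(table, path) {
  obj <- unclass(table)
  obj$S_pos <- as.vector(obj$S_pos); obj$S_neg <- as.vector(obj$S_neg)
  obj$dims <- c(length(table$theta_grid),
                if (is.null(table$theta_dot_grid)) 0L else length(table$theta_dot_grid),
                length(table$muscle_names))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a synergy table written by [write_synergy_table()]
#'
#' @param path JSON file path.
#' @return A `synergy_table`.
#' @export
read_synergy_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dims
  shape <- if (d[2] == 0L) c(d[1], d[3]) else d
  obj$S_pos <- array(obj$S_pos, shape)
  obj$S_neg <- array(obj$S_neg, shape)
  if (d[2] == 0L) obj$theta_dot_grid <- NULL
  obj$dims <- NULL
  structure(obj, class = "synergy_table")
}

#' Export synergy-ratio surfaces as a long-format data frame / CSV
#'
#' One row per (posture, muscle): columns `theta`, `muscle`, `S_pos`,
#' `S_neg`. Suitable for plotting ratio surfaces.
#'
#' @param table A posture-only `synergy_table`.
#' @param path Optional CSV output path.
#' @return The data frame, invisibly when `path` is given.
#' @export
synergy_table_to_df <- function(table, path = NULL) {
  if (!is.null(table$theta_dot_grid))
    stop("CSV export supports posture-only tables")
  df <- data.frame(
    theta = rep(table$theta_grid, times = length(table$muscle_names)),
    muscle = rep(table$muscle_names, each = length(table$theta_grid)),
    S_pos = as.vector(table$S_pos), S_neg = as.vector(table$S_neg))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
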