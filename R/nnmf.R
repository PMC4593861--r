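#' Generate an optimal-activation training matrix
#'
#' The static-synergy baseline is fitted to optimal activations rather than
#' recorded EMG: the plant follows a seeded random (sum-of-sines) motion in
#' its operational space, and at uniformly spaced sample times the demanded
#' torque is computed by inverse dynamics and shared optimally across the
#' muscles with the closed-form optimum. Antagonists are exactly zero at every
#' sample, so each column belongs to one torque direction.
#'
#' @param model A [one_dof_model()].
#' @param seed Integer seed for the random motion.
#' @param n_samples Number of sample columns.
#' @param duration Motion duration, s.
#' @param trajectory Optional [trajectory_spec()]; overrides `seed`.
#' @return An object of class `activation_matrix` with fields `A`
#'   (muscles x samples), `muscle_names`, `sample_theta`, `sample_time`.
#' @export
generate_training_data <- function(model, seed = 1, n_samples = 200,
                                   duration = 10, trajectory = NULL) {
  if (is.null(trajectory))
    trajectory <- trajectory_spec(seed = seed, duration = duration,
                                  theta_range = model$theta_range)
  times <- seq(0, trajectory$duration, length.out = n_samples)
  m <- length(model$muscles)
  A <- matrix(0, m, n_samples)
  thetas <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    tr <- trajectory_eval(trajectory, times[k])
    thetas[k] <- tr$theta
    torque <- model$inertia(tr$theta) * tr$theta_ddot +
      model$damping * tr$theta_dot - model$gravity(tr$theta)
    h <- h_vector(model, tr$theta, tr$theta_dot)
    A[, k] <- if (torque == 0) numeric(m) else optimal_activations(h, torque)
  }
  structure(list(A = A, muscle_names = model$cache$names,
                 sample_theta = thetas, sample_time = times),
            class = "activation_matrix")
}

#' Non-negative matrix factorization of an activation matrix
#'
#' Factorizes a nonnegative muscles x samples matrix `A` into `n` static
#' synergies, `A ~ S C`, by Lee-Seung multiplicative updates on the Frobenius
#' objective, with seeded nonnegative random initialization and several
#' restarts (the best factorization is kept). Reports the variance accounted
#' for, `VAF = 1 - ||A - SC||_F^2 / ||A||_F^2`.
#'
#' @param A An `activation_matrix` or a nonnegative numeric matrix.
#' @param n Number of synergies (columns of `S`).
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Convergence tolerance: stop when the per-iteration objective
#'   decrease falls below `tol` times the current objective.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed for the initializations.
#' @return An object of class `static_synergies` with nonnegative `S`
#'   (muscles x n), `C` (n x samples), and `vaf`.
#' @export
nmf_factorize <- function(A, n = 2, max_iter = 5000, tol = 1e-8,
                          n_restarts = 10, seed = 1) {
  meta <- NULL
  if (inherits(A, "activation_matrix")) { meta <- A; A <- A$A }
  A <- as.matrix(A)
  if (any(A < 0)) stop("A must be nonnegative")
  if (all(A == 0)) stop("degenerate input: A is identically zero")
  if (n < 1) stop("n must be at least 1")
  m <- nrow(A); l <- ncol(A)
  nrmA2 <- sum(A^2)
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, {
      S <- matrix(stats::runif(m * n, 0.1, 1), m, n) * max(A)
      C <- matrix(stats::runif(n * l, 0.1, 1), n, l)
      obj_prev <- Inf
      for (it in seq_len(max_iter)) {
        C <- C * (crossprod(S, A)) / (crossprod(S) %*% C + eps)
        S <- S * (A %*% t(C)) / (S %*% tcrossprod(C) + eps)
        if (it %% 10L == 0L || it == max_iter) {
          obj <- sum((A - S %*% C)^2)
          if (is.finite(obj_prev) && (obj_prev - obj) < tol * max(obj, eps)) break
          obj_prev <- obj
        }
      }
      list(S = S, C = C, obj = sum((A - S %*% C)^2))
    })
    if (is.null(best) || fit$obj < best$obj) best <- fit
  }
  structure(list(S = best$S, C = best$C, n = n,
                 vaf = 1 - best$obj / nrmA2,
                 muscle_names = if (!is.null(meta)) meta$muscle_names else rownames(A),
                 pos_col = NULL, neg_col = NULL),
            class = "static_synergies")
}

#' @export
print.static_synergies <- function(x, ...) {
  cat(sprintf("<static_synergies> %d muscles x %d synergies, VAF = %.6f%s\n",
              nrow(x$S), x$n, x$vaf,
              if (is.null(x$pos_col)) "" else
                sprintf(" (pos col %d, neg col %d)", x$pos_col, x$neg_col)))
  invisible(x)
}

#' Scale static synergies to their representative muscles
#'
#' Assigns each synergy column to the positive- or negative-torque role by
#' which representative dominates it (ties broken by the torque sign of the
#' column, `sum(S_i h_i)` at a reference posture), then divides each column
#' by its representative's entry so that the representative's weight is
#' exactly 1, multiplying the corresponding row of `C` accordingly. The
#' product `S C` is unchanged.
#'
#' @param syn A [nmf_factorize()] result with `n >= 2`.
#' @param model The source [one_dof_model()] (for representative resolution
#'   and the tie-break torque sign).
#' @param rep_pos,rep_neg Representatives (default: the model's designated
#'   ones).
#' @return The rescaled `static_synergies`, with `pos_col`/`neg_col` set.
#' @export
scale_to_representatives <- function(syn, model,
                                     rep_pos = model$rep_pos,
                                     rep_neg = model$rep_neg) {
  ip <- muscle_index(model, rep_pos); ineg <- muscle_index(model, rep_neg)
  S <- syn$S; C <- syn$C
  if (syn$n < 2) stop("need at least two synergies to assign both roles")
  h_mid <- h_vector(model, mean(model$theta_range), 0)
  score <- S[ip, ] - S[ineg, ]
  if (any(score == 0)) {
    tsign <- as.vector(h_mid %*% S)
    score[score == 0] <- tsign[score == 0]
  }
  pos_col <- which.max(score); neg_col <- which.min(score)
  if (pos_col == neg_col) stop("could not assign distinct synergy roles")
  if (S[ip, pos_col] <= 0)
    stop("scaling error: positive representative has zero weight in its synergy")
  if (S[ineg, neg_col] <= 0)
    stop("scaling error: negative representative has zero weight in its synergy")
  for (k in seq_len(syn$n)) {
    sc <- if (k == pos_col) S[ip, k] else if (k == neg_col) S[ineg, k] else max(S[, k])
    if (sc <= 0) stop("scaling error: zero synergy column")
    S[, k] <- S[, k] / sc
    C[k, ] <- C[k, ] * sc
  }
  out <- syn
  out$S <- S; out$C <- C
  out$pos_col <- pos_col; out$neg_col <- neg_col
  out$rep_pos <- ip; out$rep_neg <- ineg
  out
}

#' Write / read an activation matrix as CSV
#'
#' Muscles as rows (first column `muscle`), one column per sample labelled by
#' sample time.
#'
#' @param x An `activation_matrix`.
#' @param path CSV file path.
#' @export
write_activation_matrix <- function(x, path) {
  df <- data.frame(muscle = x$muscle_names, x$A, check.names = FALSE)
  names(df)[-1] <- sprintf("t%.6f", x$sample_time)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activation_matrix
#' @export
read_activation_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  dimnames(A) <- NULL
  structure(list(A = A, muscle_names = df$muscle,
                 sample_theta = rep(NA_real_, ncol(A)),
                 sample_time = as.numeric(sub("^t", "", names(df)[-1]))),
            class = "activation_matrix")
}
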