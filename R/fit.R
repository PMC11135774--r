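#' Fit a network dictionary online from a patch stream
#'
#' Runs the online learner: for every streamed patch, sparse-code it
#' against the current dictionary, assign it to the nearest element, update
#' the aggregated history with weight `1/t`, and update the dictionary.
#' With `convex = TRUE` (the default, online cvxNDL) the assigned element's
#' representative set absorbs the sample and one representative is pruned
#' by exhaustive leave-one-out search, so every element stays a simplex
#' combination of real sampled patches.  With `convex = FALSE` (online NDL
#' baseline) all columns are updated by projected block coordinate descent
#' on the surrogate, clipped to `[0, 1]`, with no representative sets.
#'
#' Convergence is declared when the relative change of the windowed mean
#' surrogate loss over `window` steps falls below `tol`; exhausting the
#' stream (or `max_iters`) without convergence is reported as a failure via
#' a warning, never silently.
#'
#' @param pool an `ndl_patch_pool` (or a list with `patches`, `tuples`, `k`).
#' @param K number of dictionary elements.
#' @param lambda l1 sparsity weight (default 1).
#' @param init_size number of pool patches used for initialization
#'   (default `20 * K`, at least `K * min_reps`).
#' @param min_reps minimum representatives per element at initialization.
#' @param convex `TRUE` for online cvxNDL, `FALSE` for the unconstrained
#'   online NDL baseline.
#' @param max_iters cap on online steps (default 1e6).
#' @param tol relative-change convergence tolerance on the windowed
#'   surrogate loss.
#' @param window convergence window in steps.
#' @param seed optional RNG seed (initial split is random).
#' @param qp_tol,qp_max_iter simplex QP controls.
#' @param verbose print a loss line every `verbose` steps (0 = quiet).
#' @return an `ndl_fit`: list with `dictionary` (an `ndl_dictionary`) and
#'   `state` (step count, surrogate/empirical loss traces, per-step
#'   assignments, convergence flag).
#' @export
fit_network_dictionary <- function(pool, K, lambda = 1, init_size = NULL,
                                   min_reps = 10, convex = TRUE,
                                   max_iters = 1e6, tol = 1e-4, window = 500,
                                   seed = NULL, qp_tol = 1e-8,
                                   qp_max_iter = 10000, verbose = 0) {
  if (!is.null(seed)) set.seed(seed)
  patches <- pool$patches
  tuples <- pool$tuples
  N <- nrow(patches)
  if (is.null(init_size)) init_size <- max(20 * K, K * min_reps)
  if (N <= init_size) stop("pool smaller than init_size: nothing to stream")
  init_idx <- sample.int(N, init_size)
  dict <- dict_initialize(patches[init_idx, , drop = FALSE], K, pool$k,
                          min_reps = min_reps,
                          tuples = if (!is.null(tuples)) tuples[init_idx, , drop = FALSE],
                          lambda = lambda)
  if (!convex) {
    dict$reps <- NULL; dict$rep_tuples <- NULL; dict$weights <- NULL
    dict$method <- "ndl"
  }
  # seed the aggregated history with the initialization samples, so the
  # surrogate is an average over everything observed and the first online
  # steps cannot erase the initialization structure (t counts all samples)
  fh <- 0
  for (i in seq_along(init_idx)) {
    x <- patches[init_idx[i], ]
    code <- sparse_code(x, dict$D, lambda)
    h <- update_history(dict$A_hist, dict$B_hist, code, x, i)
    dict$A_hist <- h$A_hist; dict$B_hist <- h$B_hist
    loss_i <- sum((x - dict$D %*% code)^2) + lambda * sum(abs(code))
    fh <- (1 - 1 / i) * fh + loss_i / i
  }
  t0 <- length(init_idx)
  stream <- setdiff(seq_len(N), init_idx)
  T_max <- min(length(stream), max_iters)
  f_hat <- numeric(T_max); f_emp <- numeric(T_max)
  assign_trace <- integer(T_max)
  converged <- FALSE
  fe <- fh
  for (t in seq_len(T_max)) {
    x <- patches[stream[t], ]
    code <- sparse_code(x, dict$D, lambda)
    j <- assign_nearest(x, dict$D)
    assign_trace[t] <- j
    h <- update_history(dict$A_hist, dict$B_hist, code, x, t0 + t)
    dict$A_hist <- h$A_hist; dict$B_hist <- h$B_hist
    loss_t <- sum((x - dict$D %*% code)^2) + lambda * sum(abs(code))
    w <- 1 / (t0 + t)
    fh <- (1 - w) * fh + w * loss_t
    f_hat[t] <- fh
    if (convex) {
      dict <- update_representatives(dict, j, x,
                                     tuple = if (!is.null(tuples)) tuples[stream[t], ],
                                     tol = qp_tol, max_iter = qp_max_iter)
    } else {
      dict$D <- ndl_dictionary_update(dict$D, dict$A_hist, dict$B_hist)
    }
    code_post <- sparse_code(x, dict$D, lambda)
    emp_t <- sum((x - dict$D %*% code_post)^2) + lambda * sum(abs(code_post))
    fe <- (1 - w) * fe + w * emp_t
    f_emp[t] <- fe
    dict$t <- t
    if (verbose > 0 && t %% verbose == 0)
      cat(sprintf("step %d: surrogate %.5f empirical %.5f\n", t, fh, fe))
    if (t >= 2 * window && t %% window == 0) {
      m_prev <- mean(f_hat[(t - 2 * window + 1):(t - window)])
      m_cur <- mean(f_hat[(t - window + 1):t])
      if (abs(m_cur - m_prev) / max(m_prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        f_hat <- f_hat[seq_len(t)]; f_emp <- f_emp[seq_len(t)]
        assign_trace <- assign_trace[seq_len(t)]
        break
      }
    }
  }
  if (!converged)
    warning("failure to converge within the stream/max_iters budget; ",
            "results returned but flagged unconverged")
  structure(list(dictionary = dict,
                 state = list(t = dict$t, f_hat = f_hat, f_emp = f_emp,
                              assignments = assign_trace,
                              converged = converged, lambda = lambda,
                              seed = seed)),
            class = "ndl_fit")
}

# Block coordinate descent for the unconstrained surrogate
# Tr(D A D') - 2 Tr(D B), column-wise, clipped to [0, 1] (two passes).
ndl_dictionary_update <- function(D, A_hist, B_hist, passes = 2) {
  K <- ncol(D)
  for (p in seq_len(passes)) {
    for (j in seq_len(K)) {
      if (A_hist[j, j] <= .Machine$double.eps) next
      u <- D[, j] + (B_hist[j, ] - as.numeric(D %*% A_hist[, j])) / A_hist[j, j]
      D[, j] <- pmin(pmax(u, 0), 1)
    }
  }
  D
}

#' @export
print.ndl_fit <- function(x, ...) {
  cat(sprintf("<ndl_fit> %s, %d online steps, %s (final surrogate loss %.5f)\n",
              x$dictionary$method, x$state$t,
              if (x$state$converged) "converged" else "NOT converged",
              tail2(x$state$f_hat)))
  invisible(x)
}

tail2 <- function(v) if (length(v)) v[length(v)] else NA_real_

#' Check the convex-interpretability invariants of a dictionary
#'
#' Verifies that every element reconstructs from its representatives and
#' simplex weights (`D[, j] = X_j w_j`) to the stated residual, that the
#' weights lie on the simplex, and (optionally) that every stored
#' representative is bit-identical to a patch of the originating pool.
#'
#' @param dict an `ndl_dictionary` fitted with `convex = TRUE`.
#' @param pool optional `ndl_patch_pool` for the membership check.
#' @param resid_tol reconstruction residual bound (default 1e-8).
#' @param simplex_tol simplex-sum bound (default 1e-10).
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_dictionary <- function(dict, pool = NULL, resid_tol = 1e-8,
                                simplex_tol = 1e-10) {
  stopifnot(inherits(dict, "ndl_dictionary"))
  if (is.null(dict$reps)) stop("dictionary has no representative sets")
  key <- NULL
  if (!is.null(pool))
    key <- unique(apply(pool$patches, 1, paste, collapse = ""))
  for (j in seq_len(dict$K)) {
    w <- dict$weights[[j]]
    if (any(w < -simplex_tol) || abs(sum(w) - 1) > simplex_tol)
      stop(sprintf("element %d: weights off the simplex", j))
    resid <- sqrt(sum((dict$D[, j] - dict$reps[[j]] %*% w)^2))
    if (resid > resid_tol)
      stop(sprintf("element %d: convexity residual %.2e", j, resid))
    if (any(dict$D[, j] < -resid_tol | dict$D[, j] > 1 + resid_tol))
      stop(sprintf("element %d: entries outside [0, 1]", j))
    if (!is.null(key)) {
      have <- apply(round(dict$reps[[j]]), 2, paste, collapse = "")
      if (!all(have %in% key))
        stop(sprintf("element %d: representative not found in the pool", j))
    }
  }
  invisible(TRUE)
}
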