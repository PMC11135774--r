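#' Initialize a convex dictionary from a pool of patches
#'
#' The pool is partitioned into `K` groups of at least `min_reps` patches
#' each (k-means grouping on the flattened patches, then rebalancing the
#' smallest groups by moving over the nearest members of surplus groups).
#' Each group becomes the representative set of one element, with uniform
#' simplex weights, so the initial element is the group mean.  History
#' matrices start at zero and the step counter at 0.
#'
#' @param patches numeric matrix, one flattened patch per row (N x d).
#' @param K number of dictionary elements.
#' @param k path length (so `d = k^2`).
#' @param min_reps minimum representatives per element (default 10).
#' @param tuples optional N x k matrix of the node tuples that produced the
#'   patches (kept per representative; needed for genomic summaries).
#' @param lambda l1 sparsity weight stored with the dictionary.
#' @param N_max representative capacity per element; default `2 * min_reps`
#'   (raised to `ceiling(N / K)` when needed to keep the split feasible).
#'   Initial groups are rebalanced into `[min_reps, N_max]`.
#' @return an `ndl_dictionary`.
#' @export
dict_initialize <- function(patches, K, k, min_reps = 10, tuples = NULL,
                            lambda = 1, N_max = NULL) {
  N <- nrow(patches); d <- ncol(patches)
  stopifnot(d == k * k, K >= 1, min_reps >= 1)
  if (N < K * min_reps)
    stop(sprintf("pool too small: need at least K * min_reps = %d patches, got %d",
                 K * min_reps, N))
  uniq <- unique(patches)
  if (K == 1) {
    groups <- rep(1L, N)
  } else if (nrow(uniq) < K) {
    groups <- rep_len(seq_len(K), N)   # degenerate pool: round-robin split
  } else {
    km <- suppressWarnings(stats::kmeans(patches, centers = K,
                                         nstart = 20, iter.max = 50))
    groups <- km$cluster
  }
  if (is.null(N_max)) N_max <- 2 * min_reps
  N_max <- max(N_max, ceiling(N / K))   # keep the split feasible
  # rebalance: every group in [min_reps, N_max]; surplus members of the
  # largest group migrate to the group (in need) whose mean they are
  # closest to
  sizes <- tabulate(groups, K)
  while (any(sizes < min_reps) || any(sizes > N_max)) {
    g <- if (any(sizes < min_reps)) which.min(sizes)
         else which(sizes < N_max)[which.min(sizes[sizes < N_max])]
    donor <- which.max(sizes)
    memb <- which(groups == g)
    target <- if (length(memb) > 0) colMeans(patches[memb, , drop = FALSE])
              else colMeans(patches)
    cand <- which(groups == donor)
    dist2 <- rowSums((patches[cand, , drop = FALSE] -
                      matrix(target, length(cand), d, byrow = TRUE))^2)
    groups[cand[which.min(dist2)]] <- g
    sizes <- tabulate(groups, K)
  }
  reps <- vector("list", K); rep_tuples <- vector("list", K)
  weights <- vector("list", K)
  D <- matrix(0, d, K)
  for (j in seq_len(K)) {
    idx <- which(groups == j)
    reps[[j]] <- t(patches[idx, , drop = FALSE])          # d x N_j
    rep_tuples[j] <- list(if (!is.null(tuples)) tuples[idx, , drop = FALSE])
    weights[[j]] <- rep(1 / length(idx), length(idx))
    D[, j] <- reps[[j]] %*% weights[[j]]
  }
  structure(list(D = D, reps = reps, rep_tuples = rep_tuples,
                 weights = weights,
                 A_hist = matrix(0, K, K), B_hist = matrix(0, K, d),
                 t = 0L, k = k, K = K, d = d, lambda = lambda,
                 min_reps = min_reps, N_max = N_max, method = "cvxndl"),
            class = "ndl_dictionary")
}

#' @export
print.ndl_dictionary <- function(x, ...) {
  cat(sprintf("<ndl_dictionary> %d elements, k = %d (d = %d), method = %s, t = %d\n",
              x$K, x$k, x$d, x$method, x$t))
  if (!is.null(x$reps))
    cat(sprintf("  representatives per element: %s\n",
                paste(vapply(x$reps, ncol, 1L), collapse = " ")))
  invisible(x)
}

#' Sparse-code one sample against a dictionary
#'
#' Solves the nonnegative lasso
#' `argmin_{code >= 0} ||x - D code||^2 + lambda * ||code||_1`
#' by cyclic coordinate descent.
#'
#' @param x flattened patch (length d).
#' @param D dictionary matrix (d x K).
#' @param lambda l1 weight (>= 0).
#' @param max_iter,tol coordinate-descent controls (maximum sweeps, largest
#'   coefficient change at convergence).
#' @return nonnegative coefficient vector of length K.
#' @export
sparse_code <- function(x, D, lambda = 1, max_iter = 500, tol = 1e-10) {
  if (!all(is.finite(x)) || !all(is.finite(D))) stop("non-finite inputs")
  as.numeric(cpp_nn_lasso(crossprod(D), as.numeric(crossprod(D, x)),
                          lambda, as.integer(max_iter), tol))
}

#' Index of the nearest dictionary element
#'
#' Euclidean distance on flattened patches; ties resolve to the smallest
#' index.
#'
#' @param x flattened patch.
#' @param D dictionary matrix (d x K).
#' @return element index in `1..K`.
#' @export
assign_nearest <- function(x, D) {
  which.min(colSums((D - x)^2))
}

#' Update the aggregated history matrices
#'
#' With step weight `w_t = 1/t`:
#' `A' = (1 - w_t) A + w_t code code'` and `B' = (1 - w_t) B + w_t code x'`.
#' At `t = 1` the prior history is fully replaced.
#'
#' @param A_hist K x K code Gram history.
#' @param B_hist K x d code-sample cross history.
#' @param code coefficient vector (length K).
#' @param x flattened patch (length d).
#' @param t step counter (>= 1).
#' @return list with updated `A_hist`, `B_hist`.
#' @export
update_history <- function(A_hist, B_hist, code, x, t) {
  stopifnot(t >= 1)
  w <- 1 / t
  list(A_hist = (1 - w) * A_hist + w * tcrossprod(code),
       B_hist = (1 - w) * B_hist + w * outer(code, as.numeric(x)))
}

# Linear term for the column-j restricted surrogate: the objective in
# d_j = X w is  a * w'(X'X)w + 2 w' X' g  with a = A[j,j] and
# g = sum_{l != j} A[j,l] D[:,l] - B[j,:]'.
column_linear_term <- function(D, A_hist, B_hist, j) {
  as.numeric(D[, -j, drop = FALSE] %*% A_hist[-j, j]) - as.numeric(B_hist[j, ])
}

#' Optimal simplex weights for one dictionary element
#'
#' Minimizes the quadratic surrogate `Tr(D A D') - 2 Tr(D B)` restricted to
#' column `j` (all other columns fixed) over `D[, j] = X w` with `w` on the
#' probability simplex.  Solved by accelerated projected gradient; the
#' returned solution satisfies the simplex KKT conditions to `tol`.
#'
#' @param X representative matrix (d x m).
#' @param j element index.
#' @param D current dictionary (d x K).
#' @param A_hist,B_hist aggregated history.
#' @param tol KKT residual tolerance.
#' @param max_iter iteration cap.
#' @return list with `w` (simplex vector of length m) and `objective` (the
#'   restricted surrogate value, constant terms dropped).
#' @export
solve_convex_weights <- function(X, j, D, A_hist, B_hist,
                                 tol = 1e-8, max_iter = 10000) {
  m <- ncol(X)
  if (m == 0) stop("empty representative set")
  g <- column_linear_term(D, A_hist, B_hist, j)
  res <- cpp_solve_simplex_qp(crossprod(X), as.numeric(crossprod(X, g)),
                              A_hist[j, j], rep(1 / m, m),
                              as.integer(max_iter), tol)
  list(w = as.numeric(res$w), objective = res$objective, kkt = res$kkt)
}

# Restricted surrogate value for an explicit column vector d_j.
column_objective <- function(dj, j, D, A_hist, B_hist) {
  g <- column_linear_term(D, A_hist, B_hist, j)
  A_hist[j, j] * sum(dj^2) + 2 * sum(dj * g)
}

#' Add a sample to an element's representative set and prune one member
#'
#' The sample is appended to the representative set of element `j`; every
#' leave-one-out subset of the expanded set is scored by re-solving the
#' simplex weights and evaluating the column-restricted surrogate, and the
#' removal with the smallest objective is kept.  If the best removal is the
#' newcomer itself, the element is unchanged.
#'
#' @param dict an `ndl_dictionary`.
#' @param j element index (usually from [assign_nearest()]).
#' @param x flattened patch to insert.
#' @param tuple optional node tuple of `x`.
#' @param tol,max_iter QP controls.
#' @return the updated dictionary.  The attribute `"objectives"` carries
#'   `incumbent` (restricted objective of the pre-update element) and
#'   `realized` (objective of the element after the update), for
#'   monotonicity checks.
#' @export
update_representatives <- function(dict, j, x, tuple = NULL,
                                   tol = 1e-8, max_iter = 10000) {
  stopifnot(j >= 1, j <= dict$K)
  X <- dict$reps[[j]]
  m <- ncol(X)
  Xext <- cbind(X, as.numeric(x))
  g <- column_linear_term(dict$D, dict$A_hist, dict$B_hist, j)
  a <- dict$A_hist[j, j]
  incumbent <- column_objective(dict$D[, j], j, dict$D, dict$A_hist, dict$B_hist)
  res <- cpp_best_removal(Xext, a, g, as.integer(max_iter), tol,
                          c(dict$weights[[j]], 0))
  removed <- res$removed
  if (removed == m + 1) {
    realized <- incumbent                      # newcomer rejected: unchanged
  } else {
    keep <- setdiff(seq_len(m + 1), removed)
    dict$reps[[j]] <- Xext[, keep, drop = FALSE]
    if (!is.null(dict$rep_tuples[[j]])) {
      tup <- rbind(dict$rep_tuples[[j]],
                   if (is.null(tuple)) rep(NA_integer_, dict$k) else tuple)
      dict$rep_tuples[[j]] <- tup[keep, , drop = FALSE]
    }
    dict$weights[[j]] <- as.numeric(res$w)
    dict$D[, j] <- dict$reps[[j]] %*% dict$weights[[j]]
    realized <- column_objective(dict$D[, j], j, dict$D, dict$A_hist, dict$B_hist)
  }
  attr(dict, "objectives") <- c(incumbent = incumbent, realized = realized)
  dict
}

#' Importance scores of dictionary elements
#'
#' `gamma(i) = A[i,i]^2 / sum_j A[j,j]^2` over the aggregated code Gram
#' history; scores sum to 1 and measure how often/strongly each element is
#' used.
#'
#' @param x an `ndl_dictionary` or a K x K history matrix.
#' @return numeric vector of length K summing to 1.
#' @export
importance_scores <- function(x) {
  A <- if (inherits(x, "ndl_dictionary")) x$A_hist else x
  dg <- diag(A)^2
  if (sum(dg) == 0) stop("no usage recorded: history diagonal is all zero")
  dg / sum(dg)
}

#' Interaction density of dictionary elements
#'
#' The density of an element is the mean of its `k^2` entries.
#'
#' @param x an `ndl_dictionary` or a numeric vector/matrix of flattened
#'   elements (one per column).
#' @return numeric vector of densities.
#' @export
element_density <- function(x) {
  D <- if (inherits(x, "ndl_dictionary")) x$D else as.matrix(x)
  colMeans(D)
}

#' Median genomic distance between adjacent path nodes of an element
#'
#' For every representative tuple of the element and every consecutive node
#' pair along the path, computes the absolute distance between bin
#' midpoints and returns the median (in bases).  Pairs on different
#' chromosomes are dropped.
#'
#' @param dict an `ndl_dictionary` with representative tuples, or an m x k
#'   tuple matrix.
#' @param bins bin table (`chrom`, `start`, `size`, `node_id`).
#' @param j element index (when `dict` is a dictionary).
#' @return median adjacent distance in bases.
#' @export
median_adjacent_distance <- function(dict, bins, j = NULL) {
  tuples <- if (inherits(dict, "ndl_dictionary")) {
    if (is.null(j)) stop("give an element index j")
    dict$rep_tuples[[j]]
  } else dict
  if (is.null(tuples)) stop("no node-tuple metadata stored with the representatives")
  mid <- bins$start + bins$size / 2
  chrom <- bins$chrom
  ord <- order(bins$node_id)
  mid <- mid[ord]; chrom <- chrom[ord]
  k <- ncol(tuples)
  a <- as.integer(tuples[, -k]); b <- as.integer(tuples[, -1])
  same <- chrom[a] == chrom[b]
  stats::median(abs(mid[a[same]] - mid[b[same]]))
}
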