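#' Reconstruct a network from a learned dictionary
#'
#' Samples `n_patches` path homomorphisms by MCMC (or uses the supplied
#' tuples), sparse-codes each induced patch against the dictionary, clips
#' the approximation `D code` to `[0, 1]`, and accumulates the approximated
#' entries onto the visited node pairs.  The final edge score of a pair is
#' its accumulated value divided by its visit count, so `W` is an averaged
#' local approximation of the adjacency on all visited pairs.
#'
#' @param G an `ndl_network`.
#' @param dict an `ndl_dictionary` trained with the same `k`.
#' @param n_patches number of patches (default `10 * n / k`, targeting
#'   multi-fold edge coverage).
#' @param lambda coding weight; defaults to the dictionary's training
#'   lambda.
#' @param tuples optional matrix of precomputed node tuples (one
#'   homomorphism per row) used instead of MCMC sampling.
#' @param burn_in,seed sampling controls.
#' @return an `ndl_reconstruction`: `W` (sparse symmetric score matrix),
#'   `counts` (visit counts), `n_patches`, `coverage` (fraction of true
#'   edges visited).
#' @export
reconstruct_network <- function(G, dict, n_patches = NULL, lambda = NULL,
                                tuples = NULL, burn_in = 1000, seed = NULL) {
  stopifnot(inherits(G, "ndl_network"), inherits(dict, "ndl_dictionary"))
  k <- dict$k
  if (k * k != dict$d || k < 2) stop("invalid dictionary k")
  if (is.null(lambda)) lambda <- dict$lambda
  if (is.null(tuples)) {
    if (is.null(n_patches)) n_patches <- ceiling(10 * G$n / k)
    if (n_patches == 0) {
      warning("n_patches = 0: empty reconstruction")
      W0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(G$n, G$n))
      return(structure(list(W = W0, counts = W0, visited = W0,
                            n_patches = 0L, coverage = 0),
                       class = "ndl_reconstruction"))
    }
    pool <- sample_patches(G, k, n_patches, burn_in = burn_in, seed = seed)
    tuples <- pool$tuples
    patches <- pool$patches
  } else {
    tuples <- as.matrix(tuples)
    if (ncol(tuples) != k) stop("tuple width does not match dictionary k")
    n_patches <- nrow(tuples)
    dense <- G$n <= 4000
    Ad <- if (dense) as.matrix(G$A) else NULL
    patches <- t(apply(tuples, 1, function(x) {
      p <- if (dense) Ad[x, x] else as.matrix(G$A[x, x, drop = FALSE])
      as.numeric(p)
    }))
  }
  acc <- matrix(0, G$n, G$n)
  cnt <- matrix(0, G$n, G$n)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  for (s in seq_len(n_patches)) {
    x <- tuples[s, ]
    code <- sparse_code(patches[s, ], dict$D, lambda)
    approx <- pmin(pmax(dict$D %*% code, 0), 1)
    P <- matrix(approx, k, k)
    for (r in seq_len(nrow(pairs))) {
      a <- x[pairs[r, 1]]; b <- x[pairs[r, 2]]
      if (a == b) next
      v <- P[pairs[r, 1], pairs[r, 2]]
      acc[a, b] <- acc[a, b] + v; acc[b, a] <- acc[b, a] + v
      cnt[a, b] <- cnt[a, b] + 1; cnt[b, a] <- cnt[b, a] + 1
    }
  }
  W <- acc
  nz <- cnt > 0
  W[nz] <- acc[nz] / cnt[nz]
  visited <- Matrix::drop0(Matrix::Matrix(nz * 1, sparse = TRUE))
  cov_edges <- sum((G$A != 0) & nz) / max(Matrix::nnzero(G$A), 1)
  structure(list(W = Matrix::drop0(Matrix::Matrix(W, sparse = TRUE)),
                 counts = Matrix::drop0(Matrix::Matrix(cnt, sparse = TRUE)),
                 visited = visited,
                 n_patches = n_patches, coverage = cov_edges),
            class = "ndl_reconstruction")
}

#' @export
print.ndl_reconstruction <- function(x, ...) {
  cat(sprintf("<ndl_reconstruction> %d patches, %.1f%% of true edges visited\n",
              x$n_patches, 100 * x$coverage))
  invisible(x)
}

#' Average precision of a reconstruction against the true adjacency
#'
#' Visited node pairs are ranked by their reconstructed score and compared
#' to the true edges; the score is the average of the precision at each
#' true edge in the ranking (area-under-precision-recall style).  Pairs
#' never visited by a patch are excluded.
#'
#' @param recon an `ndl_reconstruction`.
#' @param G the `ndl_network` it was computed from.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(recon, G) {
  stopifnot(inherits(recon, "ndl_reconstruction"), inherits(G, "ndl_network"))
  if (nrow(recon$W) != G$n) stop("node universe mismatch")
  vis <- as.matrix(recon$visited) > 0
  sel <- which(upper.tri(vis) & vis)
  if (length(sel) == 0) stop("no visited pairs to evaluate")
  scores <- as.matrix(recon$W)[sel]
  labels <- as.integer(as.matrix(G$A)[sel] != 0)
  ord <- order(-scores, seq_along(scores))
  rel <- labels[ord]
  n_pos <- sum(rel)
  if (n_pos == 0) stop("no true edges among visited pairs")
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec[rel == 1]) / n_pos
}
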