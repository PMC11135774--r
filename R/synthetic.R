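#' Generate a stochastic block model network
#'
#' Independent edges with probability `p_in` within blocks and `p_out`
#' between blocks; the result is restricted to its largest connected
#' component.  Nodes are ordered by block, so the community structure is
#' visible along the diagonal of the adjacency matrix.
#'
#' @param block_sizes block sizes (default three blocks of 100).
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability.
#' @param seed optional RNG seed.
#' @return an `ndl_network` with a `labels` field (block of each node) and
#'   `node_map` from [largest_component()].
#' @export
sbm_network <- function(block_sizes = c(100, 100, 100), p_in = 0.3,
                        p_out = 0.02, seed = NULL) {
  stopifnot(all(block_sizes > 0), p_out >= 0, p_out <= p_in, p_in <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[ut[, 1]] == labels[ut[, 2]], p_in, p_out)
  keep <- runif(nrow(ut)) < p
  A <- Matrix::sparseMatrix(i = ut[keep, 1], j = ut[keep, 2], x = 1,
                            dims = c(n, n))
  G <- ndl_network(A)
  G <- largest_component(G, quiet = TRUE)
  G$labels <- labels[!is.na(G$node_map)]
  G
}

#' Build a planted-motif network for parameter-recovery tests
#'
#' Places disjoint copies of each motif graph (given as k x k adjacency
#' patches) and joins the copies with sparse random linker edges: a random
#' chain over all copies guarantees connectivity when `linker` is at least
#' the number of copies minus one, and any remaining budget is spent on
#' random cross-copy edges.  Ground-truth motif and copy labels are kept.
#'
#' @param motifs list of k x k binary adjacency matrices.
#' @param copies copies per motif.
#' @param linker total number of linker edges (default: exactly enough for
#'   the connecting chain).
#' @param seed optional RNG seed.
#' @return an `ndl_network` with `labels` (motif index per node) and
#'   `copy` (copy index per node).
#' @export
planted_motif_network <- function(motifs, copies = 50, linker = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(motifs, nrow, 1L)
  n_copies <- length(motifs) * copies
  if (is.null(linker)) linker <- max(n_copies - 1, 0)
  offsets <- integer(0); labels <- integer(0); copy_id <- integer(0)
  edges <- NULL
  off <- 0L; cid <- 0L
  copy_nodes <- list()
  for (m in seq_along(motifs)) {
    Am <- motifs[[m]]
    ut <- which(upper.tri(Am) & Am != 0, arr.ind = TRUE)
    for (cc in seq_len(copies)) {
      cid <- cid + 1L
      copy_nodes[[cid]] <- off + seq_len(sizes[m])
      if (nrow(ut) > 0)
        edges <- rbind(edges, cbind(off + ut[, 1], off + ut[, 2]))
      labels <- c(labels, rep(m, sizes[m]))
      copy_id <- c(copy_id, rep(cid, sizes[m]))
      off <- off + sizes[m]
    }
  }
  n <- off
  if (n_copies > 1 && linker > 0) {
    ord <- sample(n_copies)
    chain <- min(linker, n_copies - 1)
    for (i in seq_len(chain)) {
      a <- copy_nodes[[ord[i]]]; b <- copy_nodes[[ord[i + 1]]]
      edges <- rbind(edges, cbind(a[sample.int(length(a), 1)],
                                  b[sample.int(length(b), 1)]))
    }
    extra <- linker - chain
    while (extra > 0) {
      cs <- sample(n_copies, 2)
      a <- copy_nodes[[cs[1]]]; b <- copy_nodes[[cs[2]]]
      edges <- rbind(edges, cbind(a[sample.int(length(a), 1)],
                                  b[sample.int(length(b), 1)]))
      extra <- extra - 1
    }
  }
  A <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                            dims = c(n, n))
  G <- ndl_network(A)
  G$labels <- labels
  G$copy <- copy_id
  G
}

#' Random-dictionary baseline
#'
#' Builds `K` elements as uniform-weight convex combinations of `min_reps`
#' patches drawn uniformly at random from the pool, with no regard to fit.
#' Satisfies all structural dictionary invariants and serves as a floor
#' for reconstruction quality.
#'
#' @param pool an `ndl_patch_pool`.
#' @param K number of elements.
#' @param min_reps representatives per element.
#' @param lambda coding weight stored with the dictionary.
#' @param seed optional RNG seed.
#' @return an `ndl_dictionary` with `method = "random"`.
#' @export
random_dictionary <- function(pool, K, min_reps = 10, lambda = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  patches <- pool$patches
  N <- nrow(patches); d <- ncol(patches)
  if (N < K * min_reps)
    stop(sprintf("pool too small: need at least K * min_reps = %d patches",
                 K * min_reps))
  idx <- matrix(sample.int(N, K * min_reps), K, min_reps)
  reps <- vector("list", K); rep_tuples <- vector("list", K)
  weights <- vector("list", K)
  D <- matrix(0, d, K)
  for (j in seq_len(K)) {
    reps[[j]] <- t(patches[idx[j, ], , drop = FALSE])
    rep_tuples[j] <- list(if (!is.null(pool$tuples)) pool$tuples[idx[j, ], , drop = FALSE])
    weights[[j]] <- rep(1 / min_reps, min_reps)
    D[, j] <- reps[[j]] %*% weights[[j]]
  }
  structure(list(D = D, reps = reps, rep_tuples = rep_tuples,
                 weights = weights,
                 A_hist = matrix(0, K, K), B_hist = matrix(0, K, d),
                 t = 0L, k = pool$k, K = K, d = d, lambda = lambda,
                 min_reps = min_reps, N_max = min_reps, method = "random"),
            class = "ndl_dictionary")
}
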