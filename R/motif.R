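#' Template motifs
#'
#' A template motif is a small graph `F = ([k], A_F)`; sampled subnetworks
#' must contain its topology.  Paths are the default template: they suit
#' chromatin contact networks, whose measurements are dominated by
#' proximal (path-like) contacts.
#'
#' @param k number of nodes (>= 2).
#' @return an `ndl_motif` with fields `k`, `A_F` and `type`.
#' @export
path_motif <- function(k) {
  stopifnot(k >= 2)
  A <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  structure(list(k = k, A_F = A, type = "path"), class = "ndl_motif")
}

#' @rdname path_motif
#' @details `star_motif(k)` places the hub at position 1 with `k - 1` leaves.
#' @export
star_motif <- function(k) {
  stopifnot(k >= 2)
  A <- matrix(0L, k, k)
  A[1, 2:k] <- A[2:k, 1] <- 1L
  structure(list(k = k, A_F = A, type = "star"), class = "ndl_motif")
}

# Induced k x k patch adjacency for an ordered node tuple.
patch_from_tuple <- function(G, x) {
  as.matrix(G$A[x, x, drop = FALSE])
}

# Membership test for Hom(F, G): every template edge maps to a network edge.
is_homomorphism <- function(G, motif, x) {
  k <- motif$k
  if (length(x) != k) return(FALSE)
  req <- which(motif$A_F != 0, arr.ind = TRUE)
  req <- req[req[, 1] < req[, 2], , drop = FALSE]
  all(G$A[cbind(x[req[, 1]], x[req[, 2]])] != 0)
}

#' Exhaustively enumerate homomorphisms of a motif into a small network
#'
#' A homomorphism is an ordered k-tuple of (not necessarily distinct) nodes
#' such that every motif edge maps to a network edge; it need not be
#' injective.  Brute-force search, intended as a ground-truth oracle on
#' small graphs.
#'
#' @param G an `ndl_network` with at most `max_nodes` nodes.
#' @param motif an `ndl_motif`.
#' @param max_nodes size guard (default 30).
#' @return integer matrix, one homomorphism per row.
#' @export
enumerate_homomorphisms <- function(G, motif, max_nodes = 30) {
  if (G$n > max_nodes)
    stop("network too large for exhaustive enumeration; use MCMC sampling")
  k <- motif$k
  A <- as.matrix(G$A) != 0
  out <- list()
  x <- integer(k)
  recurse <- function(pos) {
    if (pos > k) {
      out[[length(out) + 1]] <<- x
      return(invisible(NULL))
    }
    prev <- which(motif$A_F[pos, seq_len(pos - 1)] != 0)
    cand <- if (length(prev) == 0) seq_len(G$n) else {
      cs <- which(A[, x[prev[1]]])
      for (p in prev[-1]) cs <- cs[A[cs, x[p]]]
      cs
    }
    for (v in cand) {
      x[pos] <<- v
      recurse(pos + 1)
    }
  }
  recurse(1L)
  if (length(out) == 0) return(matrix(integer(0), 0, k))
  do.call(rbind, out)
}

#' Draw one homomorphism by rejection sampling
#'
#' For path motifs this is a uniform random start node followed by a
#' directed random walk of `k - 1` uniform neighbour steps (never rejects on
#' a connected graph).  For other motifs, uniform tuples are proposed and
#' rejected until one is a homomorphism (small graphs only).
#'
#' @param G a connected `ndl_network`.
#' @param motif an `ndl_motif`.
#' @param max_attempts guard for non-path motifs.
#' @return integer vector of length `k`.
#' @export
rejection_sample <- function(G, motif, max_attempts = 100000) {
  if (any(G$deg == 0)) stop("graph has isolated nodes; restrict to the largest component")
  k <- motif$k
  if (motif$type == "path") {
    x <- integer(k)
    x[1] <- sample.int(G$n, 1)
    for (i in 2:k) {
      nb <- G$adj[[x[i - 1]]]
      x[i] <- nb[sample.int(length(nb), 1L)]
    }
    return(x)
  }
  for (a in seq_len(max_attempts)) {
    x <- sample.int(G$n, k, replace = TRUE)
    if (is_homomorphism(G, motif, x)) return(x)
  }
  stop("rejection sampling failed within max_attempts")
}

# Row sums of A^(k-1) via repeated sparse mat-vec: counts of directed walks
# of length k-1 out of each node.
walk_counts <- function(G, k) {
  s <- rep(1, G$n)
  if (k >= 2) for (i in seq_len(k - 1)) s <- as.numeric(G$A %*% s)
  s
}

#' MCMC acceptance probability for the path pivot chain
#'
#' For the k-path chain with current first node `u` and proposed neighbour
#' `v`, the acceptance probability is
#' `min( (w(v)/w(u)) * (deg(u)/deg(v)), 1 )`, where `w(.)` are row sums of
#' the (k-1)-th adjacency power, i.e. counts of length-(k-1) walks.  This is
#' the Metropolis-Hastings ratio for the target in which the first node is
#' drawn proportionally to its walk count.
#'
#' @param G an `ndl_network`.
#' @param u current first node.
#' @param v proposed node; must be a neighbour of `u`.
#' @param k path length (number of nodes).
#' @param wk optional precomputed [walk counts] vector (row sums of
#'   `A^(k-1)`), to avoid recomputation in loops.
#' @return acceptance probability in `[0, 1]`.
#' @export
acceptance_probability <- function(G, u, v, k, wk = NULL) {
  if (G$A[u, v] == 0) stop("u and v are not adjacent")
  if (is.null(wk)) wk <- walk_counts(G, k)
  min((wk[v] / wk[u]) * (G$deg[u] / G$deg[v]), 1)
}

#' One step of the MCMC pivot chain over path homomorphisms
#'
#' A neighbour `v` of the current first node is proposed uniformly; it is
#' accepted with probability beta ([acceptance_probability()]).  The tail
#' of the path is then re-drawn as a directed random walk of `k - 1`
#' uniform neighbour steps (backtracking allowed).
#'
#' @param G a connected `ndl_network`.
#' @param x_t current homomorphism (integer vector).
#' @param k path length; defaults to `length(x_t)`.
#' @param wk optional precomputed walk counts.
#' @return next homomorphism (integer vector of length `k`).
#' @export
mcmc_step <- function(G, x_t, k = length(x_t), wk = NULL) {
  if (is.null(wk)) wk <- walk_counts(G, k)
  u <- x_t[1]
  nb <- G$adj[[u]]
  v <- nb[sample.int(length(nb), 1L)]
  beta <- min((wk[v] / wk[u]) * (G$deg[u] / G$deg[v]), 1)
  x1 <- if (runif(1) < beta) v else u
  x <- integer(k)
  x[1] <- x1
  for (i in 2:k) {
    nb <- G$adj[[x[i - 1]]]
    x[i] <- nb[sample.int(length(nb), 1L)]
  }
  x
}

#' Sample a stream of path patches by MCMC
#'
#' Runs the pivot chain for `burn_in` discarded steps (from a
#' rejection-sampling start) and then emits `n` consecutive samples.  Each
#' sample is the induced k x k patch adjacency of the visited node tuple,
#' flattened column-major into a length `k^2` vector.
#'
#' @param G a connected `ndl_network`.
#' @param k path length (nodes per patch).
#' @param n number of patches to emit (split over chains).
#' @param burn_in discarded initial steps per chain.
#' @param n_chains number of independent pivot chains; more chains improve
#'   coverage of weakly connected regions (default 1).
#' @param seed optional RNG seed (recorded in the pool).
#' @return an `ndl_patch_pool`: `patches` (n x k^2 binary matrix), `tuples`
#'   (n x k node ids), `k`, `n_nodes`, `burn_in`, `seed`, and `coverage`
#'   (fraction of network nodes visited).
#' @export
sample_patches <- function(G, k, n, burn_in = 1000, n_chains = 1, seed = NULL) {
  stopifnot(inherits(G, "ndl_network"), k >= 2, n >= 1, n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (any(G$deg == 0)) stop("graph has isolated nodes; restrict to the largest component")
  wk <- walk_counts(G, k)
  dense <- G$n <= 4000
  Ad <- if (dense) as.matrix(G$A) else NULL
  patches <- matrix(0L, n, k * k)
  tuples <- matrix(0L, n, k)
  per <- diff(round(seq(0, n, length.out = n_chains + 1)))
  t <- 0L
  for (ch in seq_len(n_chains)) {
    x <- rejection_sample(G, path_motif(k))
    for (b in seq_len(burn_in)) x <- mcmc_step(G, x, k, wk)
    for (s in seq_len(per[ch])) {
      x <- mcmc_step(G, x, k, wk)
      t <- t + 1L
      tuples[t, ] <- x
      p <- if (dense) Ad[x, x] else as.matrix(G$A[x, x, drop = FALSE])
      patches[t, ] <- as.integer(p)
    }
  }
  structure(list(patches = patches, tuples = tuples, k = k, n_nodes = G$n,
                 burn_in = burn_in, seed = seed, n_chains = n_chains,
                 coverage = length(unique(as.integer(tuples))) / G$n),
            class = "ndl_patch_pool")
}

#' @export
print.ndl_patch_pool <- function(x, ...) {
  cat(sprintf("<ndl_patch_pool> %d patches, k = %d (d = %d), coverage %.1f%%\n",
              nrow(x$patches), x$k, x$k^2, 100 * x$coverage))
  invisible(x)
}
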