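# Shared fixtures and independent oracles, built in code.

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1L
    A[edges[r, 2], edges[r, 1]] <- 1L
  }
  A
}

ring_graph <- function(n) {
  e <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  ndl_network(adj_from_edges(n, e))
}

triangle_graph <- function() ndl_network(adj_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3))))

single_edge_graph <- function() ndl_network(adj_from_edges(2, rbind(c(1, 2))))

# irregular connected 10-node graph used across sampling tests
toy10_graph <- function() {
  e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1), c(2, 6), c(6, 7),
             c(7, 3), c(5, 8), c(8, 9), c(9, 10), c(10, 8), c(4, 9), c(1, 6))
  ndl_network(adj_from_edges(10, e))
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  ndl_network(A)
}

# BFS connected-components oracle, independent of igraph
bfs_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# naive average-precision oracle (rank scan, double loop)
naive_average_precision <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  hits <- 0; s <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / sum(lab)
}

# exact stationary patch distribution of the pivot chain on a small graph:
# pi(tuple) = (wk[x1] / sum wk) * prod_{i<k} 1/deg(x_i), aggregated by patch
chain_patch_distribution <- function(G, k) {
  hom <- enumerate_homomorphisms(G, path_motif(k))
  wk <- rep(1, G$n)
  for (i in seq_len(k - 1)) wk <- as.numeric(G$A %*% wk)
  Ad <- as.matrix(G$A)
  probs <- apply(hom, 1, function(x) {
    p <- wk[x[1]] / sum(wk)
    for (i in seq_len(k - 1)) p <- p / G$deg[x[i]]
    p
  })
  keys <- apply(hom, 1, function(x) paste(as.integer(Ad[x, x]), collapse = ""))
  tapply(probs, keys, sum)
}

# dense simplex grid (resolution r) for the column-restricted objective
simplex_grid <- function(m, r) {
  steps <- round(1 / r)
  if (m == 2) {
    w1 <- seq(0, 1, by = r)
    return(cbind(w1, 1 - w1))
  }
  if (m == 3) {
    pts <- list()
    for (i in 0:steps) for (j in 0:(steps - i))
      pts[[length(pts) + 1]] <- c(i, j, steps - i - j) / steps
    return(do.call(rbind, pts))
  }
  stop("grid only for m <= 3")
}

column_obj_explicit <- function(w, Xr, j, D, A_hist, B_hist) {
  dj <- as.numeric(Xr %*% w)
  g <- as.numeric(D[, -j, drop = FALSE] %*% A_hist[-j, j]) - as.numeric(B_hist[j, ])
  A_hist[j, j] * sum(dj^2) + 2 * sum(dj * g)
}
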