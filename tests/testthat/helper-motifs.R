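# Planted-motif recovery harness: three k-node motif patches, each realized
# by a "concentration" community in which MCMC path walks induce the motif
# patch (almost) deterministically:
#   - clique patch  <- complete graphs (collision probability ~ 1/deg)
#   - alternating (complete bipartite) patch <- complete bipartite graphs
#   - pure path patch <- high-girth, high-degree incidence graphs, where
#     chord adjacencies are geometrically impossible
# Community sizes are chosen to balance the chain's stationary mass
# (~ degree^(k-1) x node count) across the three families.

# incidence graph of the affine plane AG(2, q): girth 6, degrees q and q+1
affine_plane_graph <- function(q) {
  pts <- expand.grid(x = 0:(q - 1), y = 0:(q - 1))
  n_pts <- q * q
  lines <- rbind(expand.grid(m = 0:(q - 1), c = 0:(q - 1), v = 0),
                 data.frame(m = 0, c = 0:(q - 1), v = 1))
  A <- matrix(0L, n_pts + nrow(lines), n_pts + nrow(lines))
  for (li in seq_len(nrow(lines))) {
    ln <- lines[li, ]
    on_line <- if (ln$v == 1) which(pts$x == ln$c)
               else which((ln$m * pts$x + ln$c) %% q == pts$y)
    A[on_line, n_pts + li] <- A[n_pts + li, on_line] <- 1L
  }
  A
}

complete_graph_adj <- function(m) matrix(1L, m, m) - diag(1L, m)

complete_bipartite_adj <- function(m) {
  A <- matrix(0L, 2 * m, 2 * m)
  A[1:m, (m + 1):(2 * m)] <- 1L
  A[(m + 1):(2 * m), 1:m] <- 1L
  A
}

# k x k patch with 1 wherever |a - b| is odd (complete bipartite motif)
parity_patch <- function(k) {
  outer(1:k, 1:k, function(a, b) as.integer(abs(a - b) %% 2 == 1))
}

planted_motif_fixture <- function(seed, copies = c(path = 1, bip = 25, clique = 20)) {
  comms <- list(path = affine_plane_graph(17),
                bip = complete_bipartite_adj(16),
                clique = complete_graph_adj(20))
  motifs_rep <- unlist(mapply(function(g, cc) rep(list(g), cc),
                              comms, copies, SIMPLIFY = FALSE),
                       recursive = FALSE)
  G <- planted_motif_network(motifs_rep, copies = 1, seed = seed)
  G$family <- rep(seq_along(comms), copies * vapply(comms, nrow, 1L))
  G
}

planted_motif_targets <- function(k) {
  list(path = path_motif(k)$A_F,
       bip = parity_patch(k),
       clique = complete_graph_adj(k))
}

# greedy matching of dictionary columns to target patches; returns the
# per-target max absolute entry deviation
greedy_match_deviation <- function(D, targets, k) {
  used <- integer(0)
  vapply(targets, function(tg) {
    devs <- vapply(seq_len(ncol(D)), function(j) {
      if (j %in% used) return(Inf)
      max(abs(matrix(D[, j], k, k) - tg))
    }, 1)
    j <- which.min(devs)
    used <<- c(used, j)
    devs[j]
  }, 1)
}
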