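#' Construct a network object from an adjacency matrix
#'
#' Networks are undirected, binary, loop-free graphs stored as a sparse
#' symmetric adjacency matrix together with a precomputed neighbour list
#' (used heavily by the samplers).
#'
#' @param A square adjacency matrix (base or \pkg{Matrix}); symmetrized,
#'   binarized, diagonal dropped.
#' @param bins optional genomic bin table (`data.frame` with columns
#'   `chrom`, `start`, `size`, `node_id`) mapping node ids to coordinates.
#' @return an object of class `ndl_network` with fields `n`, `A`
#'   (`dgCMatrix`), `adj` (list of integer neighbour vectors), `deg`,
#'   and optionally `bins`.
#' @export
ndl_network <- function(A, bins = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  A@x[] <- 1
  A <- Matrix::drop0((A + Matrix::t(A)) > 0)
  A <- methods::as(A, "dMatrix") * 1
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  n <- nrow(A)
  adj <- lapply(seq_len(n), function(i) integer(0))
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  if (nrow(idx) > 0) adj <- split(idx[, 1], factor(idx[, 2], levels = seq_len(n)))
  adj <- lapply(adj, as.integer)
  structure(list(n = n, A = A, adj = adj, deg = vapply(adj, length, 1L),
                 bins = bins),
            class = "ndl_network")
}

#' @export
print.ndl_network <- function(x, ...) {
  cat(sprintf("<ndl_network> %d nodes, %d edges\n", x$n,
              as.integer(Matrix::nnzero(x$A) / 2)))
  invisible(x)
}

#' Map genomic fragments to bins by their midpoints
#'
#' Fragments are assigned to the fixed-width bin containing their midpoint
#' `floor((start + end) / 2)`; bins are half-open `[m*size, (m+1)*size)`
#' with 0-based coordinates (BED convention).  Node ids are assigned per
#' chromosome in genomic order, contiguously from 1.
#'
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param bin_size bin width in bases.
#' @return list with `node_id` (integer vector, one per fragment), `bin`
#'   (0-based bin index per fragment) and `bins` (the bin table:
#'   `chrom`, `start`, `size`, `node_id`).
#' @export
bin_fragments <- function(fragments, bin_size = 500) {
  stopifnot(bin_size > 0)
  st <- as.numeric(fragments$start); en <- as.numeric(fragments$end)
  bad <- which(st < 0 | en <= st)
  if (length(bad) > 0)
    stop(sprintf("invalid fragment on line %d: start=%s end=%s",
                 bad[1], format(st[bad[1]]), format(en[bad[1]])))
  mid <- floor((st + en) / 2)
  bin <- floor(mid / bin_size)
  chrom <- as.character(fragments$chrom)
  key <- paste(chrom, bin, sep = "\r")
  ukey <- unique(key[order(chrom, bin)])
  node_id <- match(key, ukey)
  first <- match(ukey, key)
  bins <- data.frame(chrom = chrom[first],
                     start = bin[first] * bin_size,
                     size = bin_size,
                     node_id = seq_along(ukey),
                     stringsAsFactors = FALSE)
  list(node_id = node_id, bin = bin, bins = bins)
}

#' Build a hypergraph from binned multiway complexes
#'
#' Each complex (one multiway interaction) becomes a hyperedge after
#' deduplicating node ids within it; singleton complexes are dropped.  The
#' node universe is the set of observed ids, re-indexed contiguously.
#'
#' @param complexes list of integer vectors of node ids.
#' @return `ndl_hypergraph` with fields `n_nodes`, `hyperedges` (list of
#'   integer vectors in the new indexing) and `node_ids` (original id of
#'   each new node).
#' @export
build_hypergraph <- function(complexes) {
  if (length(complexes) == 0) stop("no complexes given")
  he <- lapply(complexes, function(e) sort(unique(as.integer(e))))
  he <- he[vapply(he, length, 1L) >= 2]
  if (length(he) == 0) stop("empty hypergraph: no complex has >= 2 distinct nodes")
  ids <- sort(unique(unlist(he)))
  he <- lapply(he, function(e) match(e, ids))
  structure(list(n_nodes = length(ids), hyperedges = he, node_ids = ids),
            class = "ndl_hypergraph")
}

#' @export
print.ndl_hypergraph <- function(x, ...) {
  cat(sprintf("<ndl_hypergraph> %d nodes, %d hyperedges (max size %d)\n",
              x$n_nodes, length(x$hyperedges),
              max(vapply(x$hyperedges, length, 1L))))
  invisible(x)
}

#' Clique-expand a hypergraph into an ordinary network
#'
#' Every hyperedge is replaced by the complete graph on its nodes, so an
#' edge (u, v) is present iff some hyperedge contains both u and v.
#'
#' @param H an `ndl_hypergraph`.
#' @param bins optional bin table carried over to the network.
#' @return an `ndl_network`.
#' @export
clique_expand <- function(H, bins = NULL) {
  stopifnot(inherits(H, "ndl_hypergraph"))
  pairs <- lapply(H$hyperedges, function(e) {
    cmb <- utils::combn(e, 2)
    cbind(cmb[1, ], cmb[2, ])
  })
  pairs <- unique(do.call(rbind, pairs))
  A <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = 1,
                            dims = c(H$n_nodes, H$n_nodes), symmetric = FALSE)
  ndl_network(A, bins = bins)
}

#' Restrict a network to its largest connected component
#'
#' Nodes are re-indexed contiguously; the mapping from old to new ids is
#' kept in the `node_map` field (`NA` for dropped nodes).  The share of
#' dropped nodes is reported.
#'
#' @param G an `ndl_network`.
#' @param quiet suppress the dropped-node message.
#' @return an `ndl_network` with an extra `node_map` field.
#' @export
largest_component <- function(G, quiet = FALSE) {
  stopifnot(inherits(G, "ndl_network"))
  if (G$n == 0) stop("empty graph")
  ig <- igraph::graph_from_adjacency_matrix(G$A, mode = "undirected")
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  node_map <- rep(NA_integer_, G$n)
  node_map[keep] <- seq_along(keep)
  dropped <- G$n - length(keep)
  if (dropped > 0 && !quiet)
    message(sprintf("largest_component: dropped %d/%d nodes (%.1f%%)",
                    dropped, G$n, 100 * dropped / G$n))
  bins <- G$bins
  if (!is.null(bins)) {
    bins <- bins[bins$node_id %in% keep, , drop = FALSE]
    bins$node_id <- node_map[bins$node_id]
  }
  out <- ndl_network(G$A[keep, keep, drop = FALSE], bins = bins)
  out$node_map <- node_map
  out
}

#' Read a hyperedge TSV (one multiway complex per line)
#'
#' Two dialects are auto-detected from the first line: fragment lists
#' (`chrom:start-end;chrom:start-end;...`) which are binned by midpoint, or
#' comma-separated integer node ids.
#'
#' @param path input file.
#' @param bin_size bin width for the fragment dialect.
#' @param max_hyperedge_size drop complexes with more nodes than this
#'   (default unlimited).
#' @return list with `hypergraph` (`ndl_hypergraph`) and `bins` (bin table
#'   or `NULL` for the integer dialect).
#' @export
read_hyperedges <- function(path, bin_size = 500, max_hyperedge_size = Inf) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no complexes given")
  bins <- NULL
  if (grepl(":", lines[1], fixed = TRUE)) {
    frag_lists <- strsplit(lines, ";", fixed = TRUE)
    frags <- do.call(rbind, lapply(seq_along(frag_lists), function(i) {
      m <- regmatches(frag_lists[[i]],
                      regexec("^\\s*([^:]+):(\\d+)-(\\d+)\\s*$", frag_lists[[i]]))
      ok <- vapply(m, length, 1L) == 4
      if (!all(ok)) stop(sprintf("malformed fragment on line %d", i))
      data.frame(chrom = vapply(m, `[`, "", 2),
                 start = as.numeric(vapply(m, `[`, "", 3)),
                 end = as.numeric(vapply(m, `[`, "", 4)),
                 line = i, stringsAsFactors = FALSE)
    }))
    bf <- bin_fragments(frags, bin_size)
    bins <- bf$bins
    complexes <- unname(split(bf$node_id, frags$line))
  } else {
    complexes <- lapply(strsplit(lines, ","), function(x) as.integer(trimws(x)))
  }
  sizes <- vapply(complexes, function(e) length(unique(e)), 1L)
  complexes <- complexes[sizes <= max_hyperedge_size]
  list(hypergraph = build_hypergraph(complexes), bins = bins)
}

#' Read an undirected edge list (2-column TSV, no header)
#'
#' Node ids may be arbitrary non-negative integers; they are re-indexed
#' contiguously and the original ids are kept in `node_ids`.
#'
#' @param path input file.
#' @return an `ndl_network` with a `node_ids` field.
#' @export
read_edgelist <- function(path) {
  el <- utils::read.table(path, header = FALSE,
                          colClasses = c("integer", "integer"))
  ids <- sort(unique(c(el[[1]], el[[2]])))
  i <- match(el[[1]], ids); j <- match(el[[2]], ids)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(ids), length(ids)))
  G <- ndl_network(A)
  G$node_ids <- ids
  G
}

#' Write a network as a 2-column undirected edge list TSV
#'
#' @param G an `ndl_network`.
#' @param path output file.
#' @export
write_edgelist <- function(G, path) {
  idx <- Matrix::which(G$A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  ids <- if (!is.null(G$node_ids)) G$node_ids else seq_len(G$n)
  utils::write.table(data.frame(ids[idx[, 1]], ids[idx[, 2]]), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bin table as a BED file
#'
#' Columns: chrom, bin start, bin end (start + size), node id.
#'
#' @param bins bin table as returned by [bin_fragments()].
#' @param path output file.
#' @export
write_bin_table <- function(bins, path) {
  utils::write.table(data.frame(bins$chrom, bins$start,
                                bins$start + bins$size, bins$node_id),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
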