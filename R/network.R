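as_binary_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric",
                                      call. = FALSE)
  if (any(diag(adj) != 0)) stop("adjacency must have zero diagonal",
                                call. = FALSE)
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                      diag = FALSE)
}

#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `ceiling(p * E)` strongest of the `E = n(n-1)/2` off-diagonal
#' connections (edge weights sorted in descending order) and sets them to 1,
#' all others to 0.  Ties are broken by ascending `(i, j)` pair order so the
#' retained edge count is deterministic.
#'
#' @param conn symmetric weighted connectivity matrix (e.g. from
#'   [wpli_matrix()]).
#' @param p proportion of edges to retain, in `(0, 1]`.
#' @return Binary 0/1 adjacency matrix with attribute `sparsity = p`.
#' @export
proportional_threshold <- function(conn, p) {
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]", call. = FALSE)
  conn <- as.matrix(conn)
  n <- nrow(conn)
  pairs <- which(upper.tri(conn), arr.ind = TRUE)
  # order pairs lexicographically by (row, col), then stably by weight
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  w <- conn[pairs]
  k <- ceiling(p * nrow(pairs))
  keep <- order(-w)[seq_len(k)]  # stable: ties fall back to pair order
  adj <- matrix(0, n, n)
  sel <- pairs[keep, , drop = FALSE]
  adj[sel] <- 1
  adj[sel[, c(2, 1), drop = FALSE]] <- 1
  dimnames(adj) <- dimnames(conn)
  attr(adj, "sparsity") <- p
  adj
}

#' Mean clustering coefficient of a binary network
#'
#' Average over nodes of the local triangle density
#' `2 T_i / (k_i (k_i - 1))`; nodes with degree below 2 contribute 0.
#'
#' @param adj binary symmetric adjacency matrix, >= 3 nodes.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj) {
  adj <- as_binary_adjacency(adj)
  if (nrow(adj) < 3) stop("need at least 3 nodes", call. = FALSE)
  ci <- igraph::transitivity(adj_to_igraph(adj), type = "local",
                             isolates = "zero")
  mean(ci)
}

#' Characteristic path length of a binary network
#'
#' Mean shortest-path distance (in edges) over all connected ordered node
#' pairs.  Disconnected pairs are excluded from the mean with a warning.
#'
#' @param adj binary symmetric adjacency matrix, >= 2 nodes.
#' @return Mean shortest path length; errors if the network has no edges.
#' @export
characteristic_path_length <- function(adj) {
  adj <- as_binary_adjacency(adj)
  if (nrow(adj) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (sum(adj) == 0) stop("network has no edges", call. = FALSE)
  d <- igraph::distances(adj_to_igraph(adj))
  off <- d[upper.tri(d)]
  if (any(!is.finite(off))) {
    warning("network is disconnected; unreachable pairs excluded")
    off <- off[is.finite(off)]
  }
  mean(off)
}

#' Graph-metric sweep across proportional thresholds
#'
#' Binarizes `conn` at every sparsity in `grid` and records the mean
#' clustering coefficient and the characteristic path length, the two
#' small-world diagnostics used to pick an operating threshold.
#'
#' @param conn symmetric weighted connectivity matrix.
#' @param grid sparsity values in `(0, 1]`; default 0.1 to 1.0 in steps
#'   of 0.1.
#' @return data.frame with columns `sparsity`, `clustering`, `path_length`
#'   and `n_edges`.
#' @export
threshold_sweep <- function(conn, grid = seq(0.1, 1, by = 0.1)) {
  if (length(grid) == 0) stop("empty sparsity grid", call. = FALSE)
  rows <- lapply(grid, function(p) {
    net <- proportional_threshold(conn, p)
    data.frame(sparsity = p,
               clustering = clustering_coefficient(net),
               path_length = suppressWarnings(
                 characteristic_path_length(net)),
               n_edges = sum(net) / 2)
  })
  do.call(rbind, rows)
}

#' Epileptic network connectivity strength (node degree)
#'
#' The number of retained connections of each node in the binarized
#' functional network: the row sums `k_i = sum_j a_ij` of the 0/1 adjacency.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return Named integer-valued vector of per-node degrees.
#' @export
encs <- function(adj) {
  adj <- as_binary_adjacency(adj)
  rowSums(adj)
}
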