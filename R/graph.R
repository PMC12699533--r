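#' Symmetric k-nearest-neighbour spatial graph
#'
#' Builds the binary adjacency of the spatial graph: an edge i-j is present
#' iff j is among the k nearest neighbours of i *or* vice versa (symmetrized
#' union). The default k = 6 matches the hexagonal neighbour count of
#' spot-array platforms. Distance ties are broken by spot index.
#'
#' @param coords numeric matrix n x 2.
#' @param k neighbours per spot, 1 <= k < n.
#' @return binary symmetric n x n matrix with zero diagonal.
#' @export
build_knn_graph <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  if (k >= n) stop("`k` must be < number of spots (", n, ")")
  adj <- matrix(0, n, n)
  # blockwise exact neighbour search; order() is stable, so ties resolve
  # to the lowest index
  block <- 1024L
  sq <- rowSums(coords^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE],
                                                   coords)
    for (ii in seq_len(e - s + 1L)) {
      i <- s + ii - 1L
      row <- d2[ii, ]
      row[i] <- Inf
      nb <- order(row)[seq_len(k)]
      adj[i, nb] <- 1
    }
  }
  adj <- pmax(adj, t(adj))
  diag(adj) <- 0
  adj
}

#' Degree-normalized adjacency
#'
#' Returns the symmetrically normalized adjacency D^{-1/2} A D^{-1/2} used by
#' the graph convolutional encoder/decoder. With `add_self_loops = TRUE`
#' (default) A is first replaced by A + I, which keeps isolated spots from
#' being annihilated by the convolution.
#'
#' @param adj binary symmetric matrix.
#' @param add_self_loops logical.
#' @return real symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(adj, add_self_loops = TRUE) {
  adj <- as.matrix(adj)
  if (!isTRUE(all.equal(adj, t(adj), tolerance = 0)))
    stop("`adj` must be symmetric")
  if (add_self_loops) diag(adj) <- diag(adj) + 1
  deg <- rowSums(adj)
  if (any(deg == 0))
    stop("graph has an isolated node with zero degree; ",
         "use add_self_loops = TRUE or connect it")
  dis <- 1 / sqrt(deg)
  adj * outer(dis, dis)
}

#' Pairwise squared Euclidean distances
#'
#' Entry (i, j) is ||s_i - s_j||^2. With `mean_normalize = TRUE` the matrix
#' is divided by its mean off-diagonal entry, making the spatial-structure
#' losses independent of the platform's coordinate units.
#'
#' @param coords numeric matrix n x 2.
#' @param mean_normalize logical; default `TRUE`.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_sqdist <- function(coords, mean_normalize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  if (mean_normalize && n > 1L) {
    m <- sum(d2) / (n * (n - 1))
    if (m > 0) d2 <- d2 / m
  }
  d2
}

#' Assemble the spatial graph structures for one slice
#'
#' Convenience wrapper producing everything the model consumes: binary
#' adjacency, normalized adjacency, squared-distance matrix, and per-spot
#' neighbour index sets (excluding the spot itself).
#'
#' @param coords numeric matrix n x 2.
#' @param k neighbours for [build_knn_graph].
#' @param add_self_loops passed to [normalize_adjacency].
#' @param mean_normalize passed to [pairwise_sqdist].
#' @return An object of class `spatial_graph` with elements `adj`,
#'   `norm_adj`, `sqdist`, `neighbor_sets`.
#' @export
spatial_graph <- function(coords, k = 6L, add_self_loops = TRUE,
                          mean_normalize = TRUE) {
  adj <- build_knn_graph(coords, k)
  structure(
    list(adj = adj,
         norm_adj = normalize_adjacency(adj, add_self_loops),
         sqdist = pairwise_sqdist(coords, mean_normalize),
         neighbor_sets = apply(adj > 0, 1L, which, simplify = FALSE)),
    class = "spatial_graph")
}
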