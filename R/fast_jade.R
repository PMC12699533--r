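#' Partition spots into hyperspots by spatial k-means
#'
#' Groups spatial locations into `m = round(fraction * n)` coarse units by
#' k-means on the coordinates. The 10-20 percent range is the recommended
#' regime; empty clusters (possible with degenerate seeds) are repaired by
#' splitting the most populous cluster.
#'
#' @param coords n x 2 coordinate matrix.
#' @param fraction hyperspots per spot, in (0, 1); `round(fraction * n)`
#'   must be >= 2 and < n.
#' @param seed integer seed for the k-means starts.
#' @return list of class `hyperspot_partition` with `assignment` (length-n,
#'   values 1..m), `m`, `centroid_coords` (m x 2), `member_counts`.
#' @export
build_hyperspots <- function(coords, fraction = 0.15, seed = 0L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (fraction <= 0) stop("`fraction` must be positive")
  m <- as.integer(round(fraction * n))
  if (m < 2L) stop("fraction * n must round to at least 2 hyperspots")
  if (m >= n) stop("hyperspot count m = ", m, " must be < n = ", n,
                   "; use the identity partition for the degenerate case")
  km <- withr::with_seed(seed, tryCatch(
    stats::kmeans(coords, centers = m, nstart = 5L, iter.max = 100L),
    error = function(e)
      stats::kmeans(coords, centers = m, nstart = 5L, iter.max = 100L,
                    algorithm = "Lloyd")))
  assignment <- km$cluster
  # repair empties by splitting the largest cluster
  counts <- tabulate(assignment, nbins = m)
  while (any(counts == 0L)) {
    empty <- which(counts == 0L)[1L]
    big <- which.max(counts)
    members <- which(assignment == big)
    take <- members[seq_len(ceiling(length(members) / 2))]
    assignment[take] <- empty
    counts <- tabulate(assignment, nbins = m)
  }
  centroids <- t(vapply(seq_len(m), function(g)
    colMeans(coords[assignment == g, , drop = FALSE]), numeric(2L)))
  structure(list(assignment = assignment, m = m,
                 centroid_coords = centroids,
                 member_counts = tabulate(assignment, nbins = m)),
            class = "hyperspot_partition")
}

#' Degenerate one-spot-per-hyperspot partition
#'
#' The identity partition (m = n) under which every coarse quantity reduces
#' exactly to its full-resolution counterpart.
#'
#' @param coords n x 2 coordinate matrix.
#' @return a `hyperspot_partition` with m = n.
#' @export
hyperspot_identity_partition <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  structure(list(assignment = seq_len(n), m = n, centroid_coords = coords,
                 member_counts = rep(1L, n)),
            class = "hyperspot_partition")
}

# m x n row-averaging operator: (A %*% h)[g, ] is the mean embedding of
# hyperspot g's members
aggregation_operator <- function(part) {
  a <- matrix(0, part$m, length(part$assignment))
  for (g in seq_len(part$m)) {
    members <- which(part$assignment == g)
    if (!length(members)) stop("hyperspot ", g, " is empty")
    a[g, members] <- 1 / length(members)
  }
  a
}

#' Average spot embeddings within hyperspots
#'
#' @param h n x d embedding matrix.
#' @param part a [build_hyperspots] partition.
#' @return m x d matrix of per-hyperspot mean embeddings.
#' @export
aggregate_embeddings <- function(h, part) {
  if (length(part$assignment) != nrow(h))
    stop("partition length does not match embeddings")
  aggregation_operator(part) %*% h
}

#' Coarse (hyperspot-level) alignment losses
#'
#' Evaluates the attention map, truncated Sinkhorn plan, and the
#' maintenance / alignment / marginal losses at hyperspot resolution: the
#' same formulas as the full-resolution ops with n1, n2 replaced by m1, m2,
#' embeddings by hyperspot means, and distances by centroid distances.
#'
#' @param h1_hyper,h2_hyper m1 x d and m2 x d hyperspot embeddings.
#' @param centroid_sqdist1,centroid_sqdist2 centroid squared-distance
#'   matrices (mean-normalized, consistent with [pairwise_sqdist]).
#' @param attn_proj d x d attention projection.
#' @param sinkhorn_iters fixed Sinkhorn iterations (default 5).
#' @param attn_scale logit scaling, `"d"` or `"sqrt_d"`.
#' @return list with `maintain`, `align`, `marginal` scalars and the coarse
#'   `plan` matrix.
#' @export
coarse_losses <- function(h1_hyper, h2_hyper, centroid_sqdist1,
                          centroid_sqdist2, attn_proj, sinkhorn_iters = 5L,
                          attn_scale = "d") {
  pa <- phase_a_pass(h1_hyper, h2_hyper, centroid_sqdist1, centroid_sqdist2,
                     attn_proj, list(lambda3 = 1, lambda4 = 1, lambda5 = 1),
                     sinkhorn_iters, attn_scale, want_grad = FALSE)
  list(maintain = pa$maintain, align = pa$align,
       marginal = max(pa$marginal, 0), plan = pa$pi)
}

#' Full-resolution plan from a coarsely trained projection
#'
#' Reuses the trained attention projection to compute spot-level attention
#' weights and balances them with fully converged Sinkhorn iterations; no
#' retraining happens at full resolution.
#'
#' @param h1,h2 full-resolution embedding matrices.
#' @param attn_proj trained d x d projection.
#' @param max_iters,tol inference Sinkhorn settings.
#' @param attn_scale logit scaling, `"d"` or `"sqrt_d"`.
#' @return a [transport_plan].
#' @export
full_resolution_plan <- function(h1, h2, attn_proj, max_iters = 200L,
                                 tol = 1e-6, attn_scale = "d") {
  sinkhorn_normalize(attention_cost(h1, h2, attn_proj, scale = attn_scale),
                     max_iters = max_iters, tol = tol)
}
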