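#' Preprocessing configuration
#'
#' @param n_hvg target size of the shared highly-variable-gene panel
#'   (>= 2). Typical panels are 1000-1500 shared HVGs.
#' @param normalize_total divide each spot by its total count and rescale to
#'   the median total (library-size normalization).
#' @param log1p apply log(1 + x) after normalization.
#' @param scale_unit_variance scale each gene to unit variance. Off by
#'   default: the decoder's ReLU output is nonnegative, so reconstruction
#'   targets should stay on the nonnegative log-normalized scale.
#' @param sqdist_mean_normalize whether downstream distance matrices are
#'   mean-normalized (recorded here for provenance; used by [spatial_graph]).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_hvg = 1500L, normalize_total = TRUE,
                              log1p = TRUE, scale_unit_variance = FALSE,
                              sqdist_mean_normalize = TRUE) {
  n_hvg <- as.integer(n_hvg)
  if (n_hvg < 2L) stop("`n_hvg` must be >= 2")
  structure(list(n_hvg = n_hvg, normalize_total = normalize_total,
                 log1p = log1p, scale_unit_variance = scale_unit_variance,
                 sqdist_mean_normalize = sqdist_mean_normalize),
            class = "preprocess_config")
}

# dispersion (variance/mean) ranking of genes on log1p library-normalized
# values; returns ranks, higher = more variable
.gene_dispersion <- function(expr) {
  mu <- colMeans(expr)
  v <- apply(expr, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  disp
}

#' Preprocess a slice pair to a shared highly-variable-gene panel
#'
#' Restricts both slices to a common ordered gene panel of at most
#' `cfg$n_hvg` genes, selected by intersecting the two slices'
#' dispersion-ranked highly variable genes, then applies (in order, when
#' enabled) per-spot total-count normalization, log1p, and per-gene
#' unit-variance scaling.
#'
#' @param a,b [slice_data] objects with raw counts.
#' @param cfg a [preprocess_config].
#' @return list of two preprocessed [slice_data] objects sharing an
#'   identical, identically ordered gene panel.
#' @export
preprocess_pair <- function(a, b, cfg = preprocess_config()) {
  stopifnot(inherits(a, "slice_data"), inherits(b, "slice_data"))
  shared <- intersect(a$gene_ids, b$gene_ids)
  if (length(shared) < 2L)
    stop("slices share fewer than 2 genes")
  ia <- match(shared, a$gene_ids)
  ib <- match(shared, b$gene_ids)
  ea <- a$expr[, ia, drop = FALSE]
  eb <- b$expr[, ib, drop = FALSE]
  if (length(shared) > cfg$n_hvg) {
    # rank genes by mean dispersion across the two slices, keep the top
    # n_hvg, preserve the shared-panel order
    score <- (rank(.gene_dispersion(ea)) + rank(.gene_dispersion(eb))) / 2
    keep <- sort(order(score, decreasing = TRUE)[seq_len(cfg$n_hvg)])
    shared <- shared[keep]
    ea <- ea[, keep, drop = FALSE]
    eb <- eb[, keep, drop = FALSE]
  }
  norm_one <- function(e) {
    if (cfg$normalize_total) {
      tot <- rowSums(e)
      target <- stats::median(tot[tot > 0])
      if (!is.finite(target) || target <= 0) target <- 1
      sf <- ifelse(tot > 0, target / tot, 0)
      e <- e * sf
    }
    if (cfg$log1p) e <- log1p(e)
    if (cfg$scale_unit_variance) {
      s <- apply(e, 2L, stats::sd)
      s[s == 0 | !is.finite(s)] <- 1
      e <- sweep(e, 2L, s, "/")
    }
    e
  }
  out_a <- slice_data(a$coords, norm_one(ea), gene_ids = shared,
                      spot_ids = a$spot_ids, labels = a$labels)
  out_b <- slice_data(b$coords, norm_one(eb), gene_ids = shared,
                      spot_ids = b$spot_ids, labels = b$labels)
  list(out_a, out_b)
}
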