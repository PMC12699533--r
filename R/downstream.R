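#' Model-based clustering of embeddings into spatial domains
#'
#' Rows are scaled to unit L2 norm, then fitted with a Gaussian mixture with
#' shared (EEE) covariance via `mclust`, the model family routinely used for
#' spatial-domain calling on SRT embeddings; hard labels come from the
#' maximum responsibility. Falls back to the spherical EII family and then
#' to k-means if the shared-covariance fit degenerates.
#'
#' @param h n x d embedding matrix.
#' @param k number of clusters (2 <= k < n). Cortex-style sections are
#'   typically clustered with k in 5..7; whole-brain developmental sections
#'   with k in 16..17.
#' @param seed integer seed (mclust's init is deterministic; the seed guards
#'   the k-means fallback).
#' @return list of class `domain_assignment` with `labels` (factor length
#'   n), `k`, `responsibilities` (n x k or NULL).
#' @export
cluster_embeddings <- function(h, k, seed = 0L) {
  h <- as.matrix(h)
  n <- nrow(h)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  if (n <= k) stop("need more spots than clusters")
  nrm <- sqrt(rowSums(h^2))
  nrm[nrm == 0] <- 1
  hn <- h / nrm
  # inactive (near-constant) latent units make the shared covariance
  # singular; they carry no cluster information and are dropped
  keep <- apply(hn, 2L, stats::sd) > 1e-10
  if (any(keep)) hn <- hn[, keep, drop = FALSE]
  # Mclust() resolves mclustBIC in the calling frame; make it visible
  # without attaching the package
  mclustBIC <- mclust::mclustBIC
  fit <- withr::with_seed(seed, {
    try_fit <- function(model, prior) tryCatch(
      mclust::Mclust(hn, G = k, modelNames = model, prior = prior,
                     verbose = FALSE),
      error = function(e) NULL)
    # conjugate prior regularizes the covariance when latent clouds are
    # nearly degenerate (e.g. unit-normalized, low intrinsic dimension)
    f <- try_fit("EEE", NULL)
    if (is.null(f)) f <- try_fit("EEE", mclust::priorControl())
    if (is.null(f)) f <- try_fit("EII", mclust::priorControl())
    f
  })
  if (!is.null(fit)) {
    labels <- factor(fit$classification)
    resp <- fit$z
  } else {
    warning("mixture fit degenerated; falling back to k-means")
    km <- withr::with_seed(seed, stats::kmeans(hn, centers = k, nstart = 10L))
    labels <- factor(km$cluster)
    resp <- NULL
  }
  structure(list(labels = labels, k = k, responsibilities = resp),
            class = "domain_assignment")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement under the permutation model;
#' 1 for identical partitions (up to renaming), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

#' Integration LISI of joint embeddings
#'
#' The local inverse Simpson's index of slice identity: for every spot, the
#' slice proportions among its Gaussian-kernel neighbours (bandwidth set per
#' spot by binary search to a fixed perplexity) are summarized as
#' 1 / sum(p_k^2) and averaged over spots. With two slices the score lives
#' in \[1, 2\]: 1 means the slices occupy separate regions of the embedding
#' space, 2 means perfect mixing.
#'
#' @param embeddings (n1 + n2) x d joint embedding matrix.
#' @param slice_ids length-(n1 + n2) identity vector with exactly two
#'   distinct values.
#' @param perplexity effective neighbourhood size (default 30).
#' @return scalar in \[1, 2\].
#' @export
ilisi_score <- function(embeddings, slice_ids, perplexity = 30) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  slice_ids <- as.factor(slice_ids)
  if (nlevels(slice_ids) != 2L)
    stop("exactly two slice identities are required")
  if (n <= perplexity)
    stop("need more than `perplexity` spots in total")
  sq <- rowSums(embeddings^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(embeddings)
  d2[d2 < 0] <- 0
  diag(d2) <- Inf
  target <- log(perplexity)
  onehot <- stats::model.matrix(~ slice_ids - 1)
  inv_simpson <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    lo <- 1e-10; hi <- 1e10; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s <= 0) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- p / s
      hcur <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(hcur - target) < 1e-5) break
      if (hcur > target) lo <- beta else hi <- beta
      beta <- (lo + hi) / 2
    }
    props <- crossprod(p, onehot)
    inv_simpson[i] <- 1 / sum(props^2)
  }
  mean(inv_simpson)
}

#' Alignment accuracy of a transport plan against domain annotations
#'
#' Each slice-1 spot whose largest transported mass reaches
#' `unaligned_threshold / (n1 * n2)` is matched to its argmax slice-2 spot;
#' the match is correct when the two spots carry the same domain label.
#' Spots below the mass threshold are "unaligned" and, under the default
#' mode, counted as incorrect (`mode = "exclude"` drops them from the
#' denominator instead).
#'
#' @param plan a [transport_plan] or matrix.
#' @param labels1,labels2 domain labels for the two slices.
#' @param unaligned_threshold multiple of the uniform mass 1/(n1 n2) a row
#'   maximum must reach (default 1).
#' @param mode `"count_wrong"` (default) or `"exclude"`.
#' @return list with `accuracy`, `n_unaligned`, and `per_domain`, a
#'   data.frame with per-domain counts plus the matched column index and
#'   mass for every labeled spot.
#' @export
alignment_accuracy <- function(plan, labels1, labels2,
                               unaligned_threshold = 1,
                               mode = c("count_wrong", "exclude")) {
  mode <- match.arg(mode)
  pi_m <- plan_matrix(plan)
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  if (length(labels1) != n1 || length(labels2) != n2)
    stop("labels must cover all spots of both slices")
  labels1 <- as.character(labels1)
  labels2 <- as.character(labels2)
  keep <- !is.na(labels1)
  if (any(!keep)) warning(sum(!keep), " unlabeled slice-1 spots excluded")
  j_star <- apply(pi_m, 1L, which.max)
  row_max <- pi_m[cbind(seq_len(n1), j_star)]
  aligned <- row_max >= unaligned_threshold / (n1 * n2)
  correct <- aligned & labels1 == labels2[j_star]
  correct[is.na(correct)] <- FALSE
  idx <- which(keep)
  denom <- if (mode == "count_wrong") length(idx) else sum(aligned[idx])
  acc <- if (denom > 0) sum(correct[idx]) / denom else 0
  detail <- data.frame(
    spot = idx, domain = labels1[idx], match = j_star[idx],
    match_domain = labels2[j_star[idx]], mass = row_max[idx],
    aligned = aligned[idx], correct = correct[idx])
  per_domain <- do.call(rbind, lapply(split(detail, detail$domain),
    function(dd) data.frame(domain = dd$domain[1], n = nrow(dd),
                            correct = sum(dd$correct),
                            unaligned = sum(!dd$aligned),
                            accuracy = mean(dd$correct))))
  rownames(per_domain) <- NULL
  list(accuracy = acc, n_unaligned = sum(!aligned[idx]),
       per_domain = per_domain, matches = detail)
}

#' One-vs-rest domain marker tests
#'
#' For each domain and gene, a Wilcoxon rank-sum test of the domain's spots
#' against all others on (preprocessed) expression, Benjamini-Hochberg
#' corrected across genes within each domain, with the difference of means
#' as the effect size. Constant genes get p = 1 and are flagged.
#'
#' @param expr n x p expression matrix (log-normalized recommended).
#' @param labels length-n domain labels (>= 2 domains, each with >= 3
#'   spots).
#' @param fdr BH threshold for the `significant` flag (default 0.05).
#' @return data.frame with columns `domain`, `gene`, `mean_in`, `mean_out`,
#'   `effect`, `p_value`, `p_adj`, `constant`, `significant`, ordered within
#'   each domain by decreasing effect among the significant genes first.
#' @export
marker_gene_test <- function(expr, labels, fdr = 0.05) {
  expr <- as.matrix(expr)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least two domains")
  if (any(table(labels) < 3L)) stop("every domain needs >= 3 spots")
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(expr)))
  out <- lapply(levels(labels), function(dom) {
    inn <- labels == dom
    res <- vapply(seq_len(ncol(expr)), function(j) {
      x_in <- expr[inn, j]; x_out <- expr[!inn, j]
      const <- stats::var(expr[, j]) == 0
      p <- if (const) 1 else
        suppressWarnings(stats::wilcox.test(x_in, x_out)$p.value)
      c(mean(x_in), mean(x_out), p, as.numeric(const))
    }, numeric(4L))
    df <- data.frame(domain = dom, gene = genes,
                     mean_in = res[1, ], mean_out = res[2, ],
                     effect = res[1, ] - res[2, ],
                     p_value = res[3, ],
                     p_adj = stats::p.adjust(res[3, ], "BH"),
                     constant = res[4, ] == 1)
    df$significant <- df$p_adj < fdr
    df[order(-df$significant, -df$effect), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
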