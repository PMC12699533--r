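#' Configuration of the synthetic paired-slice generator
#'
#' The generator emulates a pair of adjacent SRT sections: a jittered-grid
#' slice with layered (or blob/ring) domain structure and domain-specific
#' expression programs; a second slice carrying a subsample of the same
#' spots through a smooth spatial deformation, with counts re-drawn from the
#' same programs and perturbed by a per-gene multiplicative batch effect and
#' dropout.
#'
#' @param n_spots spots per slice (slice 2 gets
#'   `round(match_fraction * n_spots)`).
#' @param n_genes genes.
#' @param n_domains spatial domains (>= 2).
#' @param layout `"layers"` (horizontal laminae), `"blobs"` or `"ring"`.
#' @param signal_strength mean log-fold elevation of a domain's marker
#'   program over baseline.
#' @param noise negative-binomial dispersion (variance = mu + noise mu^2).
#' @param rotation rigid rotation (radians) applied to slice 2.
#' @param warp_amplitude,warp_frequency sinusoidal warp parameters (see
#'   [apply_deformation]); coordinates live in the unit square.
#' @param batch_sd standard deviation of the per-gene log-scale batch
#'   factors.
#' @param dropout_rate probability an entry of slice 2 is zeroed.
#' @param match_fraction fraction of slice-1 spots carried into slice 2.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_spots = 300L, n_genes = 200L, n_domains = 4L,
                             layout = c("layers", "blobs", "ring"),
                             signal_strength = 1.5, noise = 0.25,
                             rotation = 0.05, warp_amplitude = 0.03,
                             warp_frequency = 2, batch_sd = 0.15,
                             dropout_rate = 0.05, match_fraction = 1,
                             seed = 0L) {
  layout <- match.arg(layout)
  if (n_domains < 2L) stop("`n_domains` must be >= 2")
  if (n_domains > n_spots) stop("more domains than spots is infeasible")
  if (match_fraction <= 0 || match_fraction > 1)
    stop("`match_fraction` must be in (0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must be in [0, 1]")
  structure(list(n_spots = as.integer(n_spots),
                 n_genes = as.integer(n_genes),
                 n_domains = as.integer(n_domains), layout = layout,
                 signal_strength = signal_strength, noise = noise,
                 rotation = rotation, warp_amplitude = warp_amplitude,
                 warp_frequency = warp_frequency, batch_sd = batch_sd,
                 dropout_rate = dropout_rate,
                 match_fraction = match_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset generator configurations
#'
#' `"easy"`: strong domain programs, mild deformation and batch effect —
#' the regime where a reasonable method should recover domains and
#' correspondences well. `"hard"`: weak signal, strong overdispersion,
#' batch effect, dropout, deformation, and partial overlap.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param ... overrides passed to [synthetic_config].
#' @return a `synthetic_config`.
#' @export
synthetic_preset <- function(preset = c("easy", "hard"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "easy") {
    list(n_spots = 300L, n_genes = 200L, n_domains = 4L, layout = "layers",
         signal_strength = 1.5, noise = 0.25, rotation = 0.05,
         warp_amplitude = 0.03, warp_frequency = 2, batch_sd = 0.15,
         dropout_rate = 0.05, match_fraction = 1)
  } else {
    list(n_spots = 300L, n_genes = 200L, n_domains = 4L, layout = "layers",
         signal_strength = 0.6, noise = 1.0, rotation = 0.3,
         warp_amplitude = 0.1, warp_frequency = 3, batch_sd = 0.5,
         dropout_rate = 0.3, match_fraction = 0.8)
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(synthetic_config, base)
}

#' Smooth spatial deformation of coordinates
#'
#' Rotates the point cloud about its centroid, then displaces each axis by a
#' sinusoidal field of the *other* axis:
#' `x' = x + a sin(f y + phi1)`, `y' = y + a sin(f x + phi2)`, with the
#' phases drawn once from the seed. Amplitude 0 with rotation 0 is the
#' identity; any rotation alone is an isometry.
#'
#' @param coords n x 2 matrix.
#' @param rotation radians.
#' @param warp_amplitude displacement amplitude (coordinate units).
#' @param warp_frequency radians per coordinate unit.
#' @param seed integer seed for the phases.
#' @return n x 2 deformed coordinates.
#' @export
apply_deformation <- function(coords, rotation = 0, warp_amplitude = 0,
                              warp_frequency = 1, seed = 0L) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2L, ctr)
  rot <- matrix(c(cos(rotation), sin(rotation),
                  -sin(rotation), cos(rotation)), 2L, 2L)
  out <- cc %*% rot
  out <- sweep(out, 2L, ctr, "+")
  if (warp_amplitude != 0) {
    phi <- withr::with_seed(seed, stats::runif(2L, 0, 2 * pi))
    out[, 1] <- out[, 1] +
      warp_amplitude * sin(warp_frequency * out[, 2] + phi[1])
    out[, 2] <- out[, 2] +
      warp_amplitude * sin(warp_frequency * out[, 1] + phi[2])
  }
  dimnames(out) <- dimnames(coords)
  out
}

#' Multiplicative per-gene batch effect plus dropout
#'
#' Multiplies each gene column by `exp(g_j)`, `g_j ~ N(0, batch_sd^2)`, then
#' zeroes each entry independently with probability `dropout_rate`.
#' Deterministic given the seed.
#'
#' @param expr nonnegative n x p matrix.
#' @param batch_sd log-scale standard deviation.
#' @param dropout_rate in \[0, 1\].
#' @param seed integer seed.
#' @return perturbed matrix of the same shape.
#' @export
inject_batch_effect <- function(expr, batch_sd = 0, dropout_rate = 0,
                                seed = 0L) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("`expr` must be nonnegative")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("`dropout_rate` must be in [0, 1]")
  withr::with_seed(seed, {
    g <- stats::rnorm(ncol(expr), 0, batch_sd)
    out <- sweep(expr, 2L, exp(g), "*")
    if (dropout_rate > 0) {
      drop <- matrix(stats::runif(length(out)) < dropout_rate,
                     nrow(out), ncol(out))
      out[drop] <- 0
    }
    out
  })
}

# jittered sqrt-grid layout in the unit square
.grid_coords <- function(n) {
  g <- ceiling(sqrt(n))
  xy <- expand.grid(x = (seq_len(g) - 0.5) / g, y = (seq_len(g) - 0.5) / g)
  xy <- as.matrix(xy[seq_len(n), ])
  xy + matrix(stats::runif(2L * n, -0.3 / g, 0.3 / g), n, 2L)
}

.assign_domains <- function(coords, k, layout) {
  switch(layout,
    layers = {
      cut(coords[, 2], breaks = seq(0, 1, length.out = k + 1L),
          labels = FALSE, include.lowest = TRUE)
    },
    blobs = {
      centers <- cbind(stats::runif(k, 0.15, 0.85),
                       stats::runif(k, 0.15, 0.85))
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * tcrossprod(coords, centers)
      apply(d2, 1L, which.min)
    },
    ring = {
      r <- sqrt(rowSums(sweep(coords, 2L, c(0.5, 0.5))^2))
      as.integer(cut(r, breaks = stats::quantile(r, probs = seq(0, 1,
                     length.out = k + 1L)), labels = FALSE,
                     include.lowest = TRUE))
    })
}

#' Generate a synthetic slice pair with known ground truth
#'
#' Slice 1 sits on a jittered grid with domains assigned by the layout;
#' counts are negative-binomial draws around domain-specific mean programs
#' (a log-normal baseline per gene, elevated by `signal_strength` on each
#' domain's marker genes). Slice 2 carries a `match_fraction` subsample of
#' slice-1 spots through [apply_deformation]; its counts are re-drawn from
#' the same programs with the per-gene batch factors applied to the means
#' (keeping counts integral) and thinned by dropout.
#'
#' @param cfg a [synthetic_config] or [synthetic_preset].
#' @return list with `slice1`, `slice2` (both [slice_data] with `labels`
#'   set) and `truth`, a `synthetic_ground_truth` list carrying
#'   `correspondence` (slice-2 spot -> originating slice-1 spot index),
#'   `domains1`, `domains2`, `deformation`, `batch_log_factors`,
#'   `marker_sets`, `seed`.
#' @export
generate_paired_slices <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_spots; p <- cfg$n_genes; k <- cfg$n_domains
    coords1 <- .grid_coords(n)
    dom1 <- .assign_domains(coords1, k, cfg$layout)
    base_log <- stats::rnorm(p, 0.5, 0.5)
    # disjoint marker blocks, ~15% of genes per domain (at least 3 genes)
    msize <- max(3L, floor(0.15 * p))
    gene_pool <- sample.int(p)
    marker_sets <- lapply(seq_len(k), function(i)
      sort(gene_pool[((i - 1L) * msize + 1L):min(i * msize, p)]))
    mu_dom <- t(vapply(seq_len(k), function(i) {
      lm <- base_log
      lm[marker_sets[[i]]] <- lm[marker_sets[[i]]] + cfg$signal_strength
      exp(lm)
    }, numeric(p)))                               # k x p mean programs

    draw_counts <- function(domains, mu_mat) {
      mu <- mu_mat[domains, , drop = FALSE]
      size <- if (cfg$noise > 0) 1 / cfg$noise else Inf
      cnt <- if (is.finite(size))
        matrix(stats::rnbinom(length(mu), mu = mu, size = size),
               nrow(mu), ncol(mu))
      else matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
      cnt
    }

    x1 <- draw_counts(dom1, mu_dom)
    n2 <- as.integer(round(cfg$match_fraction * n))
    idx <- sort(sample.int(n, n2))
    coords2 <- apply_deformation(coords1[idx, , drop = FALSE],
                                 rotation = cfg$rotation,
                                 warp_amplitude = cfg$warp_amplitude,
                                 warp_frequency = cfg$warp_frequency,
                                 seed = cfg$seed + 1L)
    dom2 <- dom1[idx]
    batch_log <- stats::rnorm(p, 0, cfg$batch_sd)
    mu_dom2 <- sweep(mu_dom, 2L, exp(batch_log), "*")
    x2 <- draw_counts(dom2, mu_dom2)
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(x2)) < cfg$dropout_rate,
                     nrow(x2), ncol(x2))
      x2[drop] <- 0
    }
    genes <- sprintf("gene%03d", seq_len(p))
    s1 <- slice_data(coords1, x1, gene_ids = genes,
                     spot_ids = sprintf("s1_%04d", seq_len(n)),
                     labels = factor(paste0("D", dom1)))
    s2 <- slice_data(coords2, x2, gene_ids = genes,
                     spot_ids = sprintf("s2_%04d", seq_len(n2)),
                     labels = factor(paste0("D", dom2)))
    truth <- structure(
      list(correspondence = idx, domains1 = s1$labels, domains2 = s2$labels,
           deformation = list(rotation = cfg$rotation,
                              warp_amplitude = cfg$warp_amplitude,
                              warp_frequency = cfg$warp_frequency),
           batch_log_factors = batch_log, marker_sets = marker_sets,
           seed = cfg$seed),
      class = "synthetic_ground_truth")
    list(slice1 = s1, slice2 = s2, truth = truth)
  })
}
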