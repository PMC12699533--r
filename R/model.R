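#' Initialize the trainable parameters
#'
#' Per-slice one-layer GCN encoder/decoder weights, the shared attention
#' projection, and the bilinear contrastive discriminator. Weights use
#' Glorot-uniform initialization, biases start at zero, and the attention
#' projection starts at identity plus small Gaussian noise so the initial
#' attention cost is a meaningful (if untrained) bilinear form.
#'
#' @param p number of genes (input features).
#' @param d latent dimension (default 32).
#' @param seed integer seed; all draws are deterministic given it.
#' @param share_decoder if `TRUE`, slice 2 reuses slice 1's decoder tensors
#'   (the literal weight-sharing variant); default `FALSE` gives each slice
#'   its own decoder.
#' @param tied_init if `TRUE` (default) the two slices' encoder and decoder
#'   tensors start from the same draw (they diverge freely during
#'   training), so the two latent spaces are commensurate from the first
#'   epoch — the siamese-style initialization common for paired networks.
#'   `FALSE` draws every tensor independently.
#' @return list of class `jade_params` with elements `enc_weight_1`,
#'   `enc_bias_1`, `enc_weight_2`, `enc_bias_2`, `dec_weight_1`,
#'   `dec_bias_1`, `dec_weight_2`, `dec_bias_2`, `attn_proj`, `disc_weight`,
#'   `d`, `p`, `share_decoder`.
#' @export
jade_init_params <- function(p, d = 32L, seed = 0L, share_decoder = FALSE,
                             tied_init = TRUE) {
  p <- as.integer(p); d <- as.integer(d)
  glorot <- function(fin, fout) {
    a <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -a, a), fin, fout)
  }
  withr::with_seed(seed, {
    pr <- list(
      enc_weight_1 = glorot(p, d), enc_bias_1 = numeric(d),
      enc_weight_2 = glorot(p, d), enc_bias_2 = numeric(d),
      dec_weight_1 = glorot(d, p), dec_bias_1 = numeric(p),
      dec_weight_2 = glorot(d, p), dec_bias_2 = numeric(p),
      attn_proj = diag(d) + matrix(stats::rnorm(d * d, 0, 0.01), d, d),
      disc_weight = glorot(d, d),
      d = d, p = p, share_decoder = share_decoder)
    if (tied_init || share_decoder) {
      pr$dec_weight_2 <- pr$dec_weight_1
      pr$dec_bias_2 <- pr$dec_bias_1
    }
    if (tied_init) {
      pr$enc_weight_2 <- pr$enc_weight_1
      pr$enc_bias_2 <- pr$enc_bias_1
    }
    pr
  })
}

#' One-layer graph convolutional encoder
#'
#' Computes `ReLU(norm_adj %*% x %*% w + b)`: each spot aggregates its graph
#' neighbourhood's expression before the linear map and rectification.
#'
#' @param x n x p input matrix.
#' @param norm_adj n x n degree-normalized adjacency.
#' @param w p x d weight matrix.
#' @param b length-d bias, broadcast across spots.
#' @return n x d nonnegative embedding matrix.
#' @export
gcn_encode <- function(x, norm_adj, w, b) {
  if (!all(is.finite(x)) || !all(is.finite(norm_adj)))
    stop("non-finite values in encoder input")
  z <- norm_adj %*% x %*% w
  z <- sweep(z, 2L, b, "+")
  pmax(z, 0)
}

#' One-layer graph convolutional decoder
#'
#' Computes `ReLU(norm_adj %*% h %*% w + b)`, mapping embeddings back to the
#' (nonnegative) expression space.
#'
#' @param h n x d embedding matrix.
#' @param norm_adj n x n degree-normalized adjacency.
#' @param w d x p weight matrix.
#' @param b length-p bias.
#' @return n x p nonnegative reconstruction.
#' @export
gcn_decode <- function(h, norm_adj, w, b) gcn_encode(h, norm_adj, w, b)

#' Reconstruction loss for a slice pair
#'
#' `(1/n1) ||X1 - Xhat1||_F^2 + (1/n2) ||X2 - Xhat2||_F^2` (squared
#' Frobenius norms).
#'
#' @param x1,xhat1 slice-1 expression and reconstruction (matching shapes).
#' @param x2,xhat2 slice-2 expression and reconstruction.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(x1, xhat1, x2, xhat2) {
  if (!identical(dim(x1), dim(xhat1)) || !identical(dim(x2), dim(xhat2)))
    stop("reconstruction shapes do not match the inputs")
  sum((x1 - xhat1)^2) / nrow(x1) + sum((x2 - xhat2)^2) / nrow(x2)
}

#' Local spatial proxy of each spot
#'
#' Row i of the result is the mean embedding over i's graph neighbours
#' (excluding i itself); the positive target of the contrastive objective.
#'
#' @param h n x d embedding matrix.
#' @param neighbor_sets list of integer neighbour index vectors, as in
#'   [spatial_graph].
#' @return n x d matrix of neighbourhood means.
#' @export
neighborhood_proxy <- function(h, neighbor_sets) {
  n <- nrow(h)
  if (length(neighbor_sets) != n)
    stop("`neighbor_sets` length does not match embeddings")
  if (any(lengths(neighbor_sets) == 0L))
    stop("a spot has an empty neighbour set; the graph is degenerate")
  proxy_operator(neighbor_sets, n) %*% h
}

# row-normalized (no self-loop) adjacency as a dense operator P with
# P %*% h = neighbourhood means
proxy_operator <- function(neighbor_sets, n) {
  p_op <- matrix(0, n, n)
  for (i in seq_len(n)) p_op[i, neighbor_sets[[i]]] <-
      1 / length(neighbor_sets[[i]])
  p_op
}

#' Row-shuffled negative embeddings
#'
#' Returns `h` with rows permuted uniformly at random (deterministic given
#' `rng_seed`), destroying the spatial coherence the contrastive
#' discriminator relies on.
#'
#' @param h n x d embedding matrix (n >= 2).
#' @param rng_seed integer seed.
#' @return list with `h_neg` (permuted matrix) and `perm` (the permutation).
#' @export
shuffle_negatives <- function(h, rng_seed = 0L) {
  n <- nrow(h)
  if (n < 2L) stop("need at least 2 rows to shuffle")
  perm <- withr::with_seed(rng_seed, sample.int(n))
  list(h_neg = h[perm, , drop = FALSE], perm = perm)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Graph-infomax contrastive loss for one slice
#'
#' The bilinear discriminator scores each (embedding, proxy) pair as
#' `sigmoid(h_i' W r_i)`; the loss is the binary cross-entropy separating
#' true pairs from row-shuffled negatives, averaged over spots. Scores are
#' clamped to `(1e-7, 1 - 1e-7)` before the logs. A zero discriminator gives
#' the chance level `2 log 2` exactly.
#'
#' @param h,proxies positive embeddings and their neighbourhood proxies
#'   (n x d each).
#' @param h_neg,proxies_neg the shuffled negatives and their proxies.
#' @param disc_weight d x d discriminator matrix.
#' @return nonnegative scalar (one slice's contribution; sum over slices for
#'   the total contrastive loss).
#' @export
contrastive_loss <- function(h, proxies, h_neg, proxies_neg, disc_weight) {
  eps <- 1e-7
  s_pos <- sigmoid(rowSums((h %*% disc_weight) * proxies))
  s_neg <- sigmoid(rowSums((h_neg %*% disc_weight) * proxies_neg))
  s_pos <- pmin(pmax(s_pos, eps), 1 - eps)
  s_neg <- pmin(pmax(s_neg, eps), 1 - eps)
  -mean(log(s_pos) + log(1 - s_neg))
}
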