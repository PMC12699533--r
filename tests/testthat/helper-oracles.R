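# independent brute-force implementations used as oracles, plus small
# shared fixtures; all deliberately loop-based and separate from the
# package's vectorized code paths

oracle_gcn <- function(x, a, w, b) {
  n <- nrow(x); p <- ncol(x); d <- ncol(w)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d)) {
    acc <- b[j]
    for (k in seq_len(n)) for (l in seq_len(p))
      acc <- acc + a[i, k] * x[k, l] * w[l, j]
    out[i, j] <- max(acc, 0)
  }
  out
}

oracle_attention <- function(h1, h2, m, sign = 1) {
  n1 <- nrow(h1); n2 <- nrow(h2); d <- ncol(h1)
  u1 <- h1 %*% m; u2 <- h2 %*% m
  logits <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    logits[i, j] <- sign * sum(u1[i, ] * u2[j, ]) / d
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    e <- exp(logits[i, ] - max(logits[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

# independent iterative-scaling solver (row-first order; same fixed point)
oracle_sinkhorn <- function(c_m, tol = 1e-12, iters = 5000L) {
  n1 <- nrow(c_m); n2 <- ncol(c_m)
  pi_m <- c_m
  for (t in seq_len(iters)) {
    for (i in seq_len(n1)) pi_m[i, ] <- pi_m[i, ] * (1 / n1) / sum(pi_m[i, ])
    for (j in seq_len(n2)) pi_m[, j] <- pi_m[, j] * (1 / n2) / sum(pi_m[, j])
    dev <- max(abs(rowSums(pi_m) - 1 / n1), abs(colSums(pi_m) - 1 / n2))
    if (dev < tol) break
  }
  pi_m
}

oracle_maintain <- function(pi_m, d1, d2) {
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  t1 <- matrix(0, n1, n1)
  for (i in seq_len(n1)) for (j in seq_len(n1))
    for (k in seq_len(n2)) for (l in seq_len(n2))
      t1[i, j] <- t1[i, j] + pi_m[i, k] * d2[k, l] * pi_m[j, l]
  t2 <- matrix(0, n2, n2)
  for (i in seq_len(n2)) for (j in seq_len(n2))
    for (k in seq_len(n1)) for (l in seq_len(n1))
      t2[i, j] <- t2[i, j] + pi_m[k, i] * d1[k, l] * pi_m[l, j]
  sqrt(sum((d1 - n2^2 * t1)^2)) / n1 + sqrt(sum((d2 - n1^2 * t2)^2)) / n2
}

oracle_align <- function(pi_m, h1, h2) {
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  r1 <- h1 - n2 * (pi_m %*% h2)
  r2 <- h2 - n1 * (t(pi_m) %*% h1)
  s1 <- 0
  for (v in as.vector(r1)) s1 <- s1 + v^2
  s2 <- 0
  for (v in as.vector(r2)) s2 <- s2 + v^2
  sqrt(s1) / n1 + sqrt(s2) / n2
}

oracle_contrastive <- function(h, r, hn, rn, phi) {
  n <- nrow(h)
  loss <- 0
  for (i in seq_len(n)) {
    sp <- 1 / (1 + exp(-sum(h[i, ] * (phi %*% r[i, ]))))
    sn <- 1 / (1 + exp(-sum(hn[i, ] * (phi %*% rn[i, ]))))
    sp <- min(max(sp, 1e-7), 1 - 1e-7)
    sn <- min(max(sn, 1e-7), 1 - 1e-7)
    loss <- loss - (log(sp) + log(1 - sn)) / n
  }
  loss
}

oracle_proxy <- function(h, nbrs) {
  out <- h * 0
  for (i in seq_len(nrow(h)))
    out[i, ] <- colMeans(h[nbrs[[i]], , drop = FALSE])
  out
}

# permutation-model ARI straight from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

rand_graph_env <- function(n, p, d, seed) {
  set.seed(seed)
  g <- spatial_graph(matrix(runif(n * 2), n, 2), k = min(2L, n - 1L))
  list(g = g, x = matrix(abs(rnorm(n * p)), n, p),
       h = matrix(rnorm(n * d), n, d))
}

# one easy-preset training run shared by the slower tests; memoized per
# test session
.jade_cache <- new.env(parent = emptyenv())

easy_fixture <- function() {
  if (!is.null(.jade_cache$easy)) return(.jade_cache$easy)
  sim <- generate_paired_slices(synthetic_preset("easy", seed = 0L))
  pp <- preprocess_pair(sim$slice1, sim$slice2,
                        preprocess_config(n_hvg = 200))
  fit <- train_jade(pp[[1]], pp[[2]],
                    config = jade_config(epochs = 300L, seed = 0L))
  .jade_cache$easy <- list(sim = sim, pp = pp, fit = fit)
  .jade_cache$easy
}
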