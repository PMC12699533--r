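test_that("GCN encoder/decoder match trivial cases and the loop oracle", {
  set.seed(21)
  # zero map and ReLU clipping
  x <- matrix(rnorm(12), 4, 3)
  na <- diag(4)
  expect_equal(gcn_encode(x, na, matrix(0, 3, 2), c(0, 0)),
               matrix(0, 4, 2))
  expect_equal(gcn_encode(matrix(2, 1, 1), diag(1),
                          matrix(-3, 1, 1), 1), matrix(0, 1, 1))
  # identity decode on nonnegative input
  h <- matrix(abs(rnorm(8)), 4, 2)
  expect_equal(gcn_decode(h, diag(4), diag(2), c(0, 0)), h)
  # random instances vs brute force
  for (rep in 1:5) {
    env <- rand_graph_env(5, 3, 2, 100 + rep)
    w <- matrix(rnorm(6), 3, 2)
    b <- rnorm(2)
    expect_equal(gcn_encode(env$x, env$g$norm_adj, w, b),
                 oracle_gcn(env$x, env$g$norm_adj, w, b),
                 tolerance = 1e-10)
    wd <- matrix(rnorm(6), 2, 3)
    bd <- rnorm(3)
    expect_equal(unname(gcn_decode(env$h, env$g$norm_adj, wd, bd)),
                 oracle_gcn(env$h, env$g$norm_adj, wd, bd),
                 tolerance = 1e-10)
  }
  expect_true(all(gcn_encode(env$x, env$g$norm_adj, w, b) >= 0))
})

test_that("reconstruction loss follows the per-slice normalized square sum", {
  x1 <- matrix(c(1, 2), 1, 2)
  expect_equal(reconstruction_loss(x1, x1, x1, x1), 0)
  expect_equal(reconstruction_loss(x1, matrix(0, 1, 2), x1, x1), 5)
  set.seed(22)
  a <- matrix(rnorm(12), 3, 4); ah <- matrix(rnorm(12), 3, 4)
  b <- matrix(rnorm(10), 5, 2); bh <- matrix(rnorm(10), 5, 2)
  l1 <- reconstruction_loss(a, ah, b, bh)
  # doubling both residuals quadruples the loss
  l2 <- reconstruction_loss(a, a + 2 * (ah - a), b, b + 2 * (bh - b))
  expect_equal(l2, 4 * l1, tolerance = 1e-12)
  expect_error(reconstruction_loss(a, ah[, 1:2], b, bh), "shapes")
})

test_that("neighbourhood proxies are neighbour means excluding self", {
  h <- matrix(c(0, 2), 2, 1)
  expect_equal(neighborhood_proxy(h, list(2L, 1L)), matrix(c(2, 0), 2, 1))
  v <- c(1.5, -2)
  hc <- matrix(rep(v, each = 4), 4, 2)
  g <- spatial_graph(matrix(runif(8), 4, 2), k = 2)
  expect_equal(neighborhood_proxy(hc, g$neighbor_sets), hc)
  set.seed(23)
  env <- rand_graph_env(7, 2, 3, 55)
  expect_equal(neighborhood_proxy(env$h, env$g$neighbor_sets),
               oracle_proxy(env$h, env$g$neighbor_sets),
               tolerance = 1e-12)
  expect_error(neighborhood_proxy(env$h, c(env$g$neighbor_sets[-7],
                                           list(integer(0)))), "empty")
})

test_that("negative shuffling is seeded, permutation-valid and binary at n=2", {
  set.seed(24)
  h <- matrix(rnorm(12), 6, 2)
  s1 <- shuffle_negatives(h, rng_seed = 9L)
  s2 <- shuffle_negatives(h, rng_seed = 9L)
  expect_identical(s1$perm, s2$perm)
  expect_identical(s1$h_neg, s2$h_neg)
  expect_equal(s1$h_neg[order(s1$perm), ], h)
  h2 <- matrix(1:4, 2, 2)
  for (seed in 1:5) {
    out <- shuffle_negatives(h2, seed)$h_neg
    expect_true(identical(out, h2) || identical(out, h2[2:1, ]))
  }
})

test_that("contrastive loss hits the chance level and the loop oracle", {
  set.seed(25)
  h <- matrix(rnorm(18), 6, 3)
  g <- spatial_graph(matrix(runif(12), 6, 2), k = 2)
  r <- neighborhood_proxy(h, g$neighbor_sets)
  sh <- shuffle_negatives(h, 1L)
  rn <- neighborhood_proxy(sh$h_neg, g$neighbor_sets)
  # zero discriminator: every score 0.5 -> 2 log 2 per slice
  expect_equal(contrastive_loss(h, r, sh$h_neg, rn, matrix(0, 3, 3)),
               2 * log(2), tolerance = 1e-12)
  phi <- matrix(rnorm(9), 3, 3)
  expect_equal(contrastive_loss(h, r, sh$h_neg, rn, phi),
               oracle_contrastive(h, r, sh$h_neg, rn, phi),
               tolerance = 1e-10)
  # perfect-discrimination limit: positives score high, negatives low
  expect_lt(contrastive_loss(h, h, h, -h, diag(3) * 50), 1e-4)
})

test_that("model losses are invariant to within-slice spot permutation", {
  set.seed(26)
  n <- 8
  env <- rand_graph_env(n, 4, 3, 77)
  w <- matrix(rnorm(12), 4, 3)
  b <- rnorm(3)
  h <- gcn_encode(env$x, env$g$norm_adj, w, b)
  perm <- sample(n)
  hp <- gcn_encode(env$x[perm, ], env$g$norm_adj[perm, perm], w, b)
  expect_equal(hp, h[perm, ], tolerance = 1e-12)
  # reconstruction loss under the same permutation of both arguments
  xh <- gcn_decode(h, env$g$norm_adj, t(w), rnorm(4))
  expect_equal(reconstruction_loss(env$x, xh, env$x, xh),
               reconstruction_loss(env$x[perm, ], xh[perm, ],
                                   env$x, xh), tolerance = 1e-12)
  # contrastive: permute embeddings, proxies and negatives coherently
  r <- neighborhood_proxy(h, env$g$neighbor_sets)
  sh <- shuffle_negatives(h, 3L)
  rn <- neighborhood_proxy(sh$h_neg, env$g$neighbor_sets)
  phi <- matrix(rnorm(9), 3, 3)
  expect_equal(contrastive_loss(h[perm, ], r[perm, ], sh$h_neg[perm, ],
                                rn[perm, ], phi),
               contrastive_loss(h, r, sh$h_neg, rn, phi),
               tolerance = 1e-12)
})

test_that("parameter initialization is seeded and shape-consistent", {
  p1 <- jade_init_params(10, 4, seed = 1)
  p2 <- jade_init_params(10, 4, seed = 1)
  expect_identical(p1, p2)
  expect_equal(dim(p1$enc_weight_1), c(10L, 4L))
  expect_equal(dim(p1$attn_proj), c(4L, 4L))
  expect_true(all(vapply(p1[1:10], function(x) all(is.finite(x)), TRUE)))
  p3 <- jade_init_params(10, 4, seed = 1, tied_init = FALSE)
  expect_false(identical(p3$enc_weight_1, p3$enc_weight_2))
})
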