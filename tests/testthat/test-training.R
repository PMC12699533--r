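small_pair <- function(n = 60L, seed = 2L) {
  sim <- generate_paired_slices(synthetic_config(
    n_spots = n, n_genes = 30L, n_domains = 3L, seed = seed))
  preprocess_pair(sim$slice1, sim$slice2, preprocess_config(n_hvg = 30L))
}

test_that("lambda3 selection follows the pseudo-bulk similarity rule", {
  set.seed(51)
  x <- matrix(rpois(200, 4), 20, 10)
  expect_equal(select_lambda3(x, x), 2.0)
  # anti-correlated pseudo-bulks clamp at the lower bound
  pb <- colMeans(x)
  x2 <- matrix(rep(max(pb) + min(pb) - pb, each = 20), 20, 10)
  expect_equal(select_lambda3(x, x2), 0.2, tolerance = 1e-9)
  for (rep in 1:10) {
    a <- matrix(rexp(150), 15, 10)
    b <- matrix(rexp(150), 15, 10)
    l3 <- select_lambda3(a, b)
    expect_gte(l3, 0.2)
    expect_lte(l3, 2.0)
  }
  expect_warning(sel <- select_lambda3(matrix(1, 5, 4), x[1:5, 1:4]),
                 "zero-variance")
  expect_equal(sel, 0.2)
})

test_that("total loss combines components with the standard weights", {
  w <- loss_weights(lambda3 = 1)
  comp <- c(contrastive = 1, recon = 1, maintain = 1, align = 1,
            marginal = 1)
  expect_equal(total_loss(comp, w), 13.1)
  expect_equal(total_loss(comp * 0, w), 0)
  # linear in each component with slope equal to its weight
  for (nm in names(comp)) {
    bumped <- comp
    bumped[nm] <- 3
    slope <- (total_loss(bumped, w) - total_loss(comp, w)) / 2
    want <- c(contrastive = 1, recon = 10, maintain = 1, align = 0.1,
              marginal = 1)[[nm]]
    expect_equal(slope, want, tolerance = 1e-12)
  }
  comp["recon"] <- NA
  expect_error(total_loss(comp, w), "recon")
})

test_that("training is bitwise deterministic given the seed", {
  pp <- small_pair()
  cfg <- jade_config(epochs = 25L, seed = 3L, k_neighbors = 4L,
                     latent_dim = 8L)
  f1 <- train_jade(pp[[1]], pp[[2]], config = cfg)
  f2 <- train_jade(pp[[1]], pp[[2]], config = cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$plan$pi, f2$plan$pi)
  expect_identical(f1$embeddings, f2$embeddings)
})

test_that("loss history is finite, nonnegative, one row per epoch", {
  pp <- small_pair()
  fit <- train_jade(pp[[1]], pp[[2]],
                    config = jade_config(epochs = 30L, seed = 1L,
                                         k_neighbors = 4L, latent_dim = 8L,
                                         early_stop_patience = Inf))
  lh <- fit$loss_history
  expect_equal(nrow(lh), 30L)
  expect_true(all(is.finite(as.matrix(lh))))
  expect_true(all(as.matrix(lh[, -1]) >= 0))
  expect_equal(lh$epoch, 1:30)
})

test_that("with alignment weights zeroed the model degenerates to
           contrastive autoencoders and the plan is Sinkhorn of attention", {
  pp <- small_pair()
  cfg <- jade_config(epochs = 20L, seed = 4L, k_neighbors = 4L,
                     latent_dim = 8L)
  fit <- train_jade(pp[[1]], pp[[2]], config = cfg,
                    weights = loss_weights(lambda3 = 0, lambda4 = 0,
                                           lambda5 = 0))
  ref <- sinkhorn_normalize(
    attention_cost(fit$embeddings$h1, fit$embeddings$h2,
                   fit$params$attn_proj),
    max_iters = cfg$sinkhorn_eval_iters, tol = cfg$sinkhorn_tol)
  expect_equal(unname(fit$plan$pi), ref$pi, tolerance = 1e-12)
  # the attention projection received zero gradient throughout
  init <- jade_init_params(pp[[1]]$p, 8L, seed = 4L)
  expect_equal(fit$params$attn_proj, init$attn_proj, tolerance = 1e-12)
})

test_that("inference-time plans satisfy the transport contract", {
  pp <- small_pair()
  fit <- train_jade(pp[[1]], pp[[2]],
                    config = jade_config(epochs = 15L, seed = 5L,
                                         k_neighbors = 4L, latent_dim = 8L))
  expect_lt(fit$plan$marginal_err, 1e-6)
  expect_true(fit$plan$converged)
  expect_equal(sum(fit$plan$pi), 1, tolerance = 1e-9)
  n1 <- pp[[1]]$n; n2 <- pp[[2]]$n
  expect_equal(rowSums(fit$plan$pi), stats::setNames(rep(1 / n1, n1),
                                                     pp[[1]]$spot_ids),
               tolerance = 1e-6)
  expect_equal(colSums(fit$plan$pi), stats::setNames(rep(1 / n2, n2),
                                                     pp[[2]]$spot_ids),
               tolerance = 1e-6)
})

test_that("unpreprocessed gene panels are rejected", {
  sim <- generate_paired_slices(synthetic_config(n_spots = 20L,
                                                 n_genes = 10L, seed = 1L))
  s2 <- sim$slice2
  s2$gene_ids <- rev(s2$gene_ids)
  expect_error(train_jade(sim$slice1, s2), "identical shared gene panel")
})
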