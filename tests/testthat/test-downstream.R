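test_that("clustering separates well-separated Gaussian blobs exactly", {
  set.seed(71)
  # distinct directions (clustering L2-normalizes rows first)
  h <- rbind(cbind(rnorm(50, 3, 0.05), rnorm(50, 0, 0.05)),
             cbind(rnorm(50, 0, 0.05), rnorm(50, 3, 0.05)))
  truth <- rep(1:2, each = 50)
  cl <- cluster_embeddings(h, k = 2, seed = 1L)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_equal(cl$k, 2L)
  if (!is.null(cl$responsibilities))
    expect_equal(rowSums(cl$responsibilities), rep(1, 100),
                 tolerance = 1e-8)
  # deterministic given seed
  cl2 <- cluster_embeddings(h, k = 2, seed = 1L)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_embeddings(h, k = 1), "k")
})

test_that("ARI is 1 on relabelings, symmetric, and matches the formula", {
  a <- rep(c("x", "y", "z"), times = c(5, 7, 9))
  expect_equal(adjusted_rand_index(a, a), 1)
  relabeled <- c(x = "beta", y = "gamma", z = "alpha")[a]
  expect_equal(adjusted_rand_index(a, relabeled), 1)
  set.seed(72)
  b <- sample(1:3, length(a), replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
               tolerance = 1e-12)
  expect_error(adjusted_rand_index(a, b[-1]), "equal length")
})

test_that("ARI of independent labelings is centred at zero", {
  set.seed(73)
  aris <- vapply(1:100, function(s) {
    a <- sample(1:4, 1000, replace = TRUE)
    b <- sample(1:4, 1000, replace = TRUE)
    adjusted_rand_index(a, b)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("iLISI spans separated to fully mixed configurations", {
  set.seed(74)
  # two distant blobs, one slice each: pure neighbourhoods
  e1 <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
              matrix(rnorm(200, 50, 0.1), 100, 2))
  ids <- rep(c("a", "b"), each = 100)
  sep <- ilisi_score(e1, ids)
  expect_lt(sep, 1.05)
  # random identities inside one blob: near-perfect mixing
  e2 <- matrix(rnorm(400), 200, 2)
  mixed <- ilisi_score(e2, sample(ids))
  expect_gt(mixed, 1.9)
  for (score in c(sep, mixed)) {
    expect_gte(score, 1)
    expect_lte(score, 2)
  }
  # rigid transformation of the embedding cloud leaves the score unchanged
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(ilisi_score(sweep(e1 %*% rot, 2, c(5, -3), "+"), ids), sep,
               tolerance = 1e-6)
  expect_error(ilisi_score(e1[1:20, ], rep(c("a", "b"), 10),
                           perplexity = 30), "perplexity")
})

test_that("alignment accuracy handles diagonal, tied and thresholded plans", {
  n <- 6
  labs <- factor(rep(c("A", "B", "C"), each = 2))
  res <- alignment_accuracy(diag(n) / n, labs, labs)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_unaligned, 0L)
  # uniform plan: which.max takes the lowest index, so every spot matches
  # spot 1 and only spots sharing its label are correct
  uni <- matrix(1 / n^2, n, n)
  res_u <- alignment_accuracy(uni, labs, labs)
  expect_equal(res_u$accuracy, mean(labs == labs[1]))
  # a threshold above every row maximum marks everything unaligned
  res_t <- alignment_accuracy(uni, labs, labs, unaligned_threshold = 2)
  expect_equal(res_t$accuracy, 0)
  expect_equal(res_t$n_unaligned, n)
  # excluded mode drops unaligned spots from the denominator
  res_e <- alignment_accuracy(uni, labs, labs, unaligned_threshold = 2,
                              mode = "exclude")
  expect_equal(res_e$accuracy, 0)
  # per-domain table covers every labeled domain
  expect_setequal(res$per_domain$domain, c("A", "B", "C"))
  expect_equal(sum(res$per_domain$n), n)
})

test_that("alignment accuracy is invariant to consistent column permutation", {
  set.seed(75)
  n <- 10
  pi_m <- matrix(runif(n * n), n, n)
  pi_m <- pi_m / sum(pi_m)
  l1 <- sample(c("A", "B"), n, TRUE)
  l2 <- sample(c("A", "B"), n, TRUE)
  perm <- sample(n)
  a0 <- alignment_accuracy(pi_m, l1, l2)$accuracy
  a1 <- alignment_accuracy(pi_m[, perm], l1, l2[perm])$accuracy
  expect_equal(a0, a1)
})

test_that("planted markers are recovered and identical expression yields none", {
  set.seed(76)
  n <- 60; p <- 15
  labs <- rep(c("A", "B"), each = 30)
  expr <- matrix(rpois(n * p, 5), n, p)
  colnames(expr) <- paste0("g", 1:p)
  expr[labs == "B", 1] <- 0  # gene g1 expressed only in domain A
  res <- marker_gene_test(expr, labs, fdr = 0.05)
  top_a <- res[res$domain == "A", ][1, ]
  expect_equal(top_a$gene, "g1")
  expect_lt(top_a$p_adj, 0.05)
  expect_true(top_a$significant)
  # constant expression across domains: nothing significant
  same <- matrix(3, n, p)
  res0 <- marker_gene_test(same, labs)
  expect_equal(sum(res0$significant), 0)
  expect_true(all(res0$constant))
})

test_that("marker test false-positive rate respects the FDR under the null", {
  set.seed(77)
  n <- 40; p <- 20
  expr <- matrix(rpois(n * p, 6), n, p)
  hits <- vapply(1:60, function(s) {
    labs <- sample(rep(c("A", "B"), each = n / 2))
    res <- marker_gene_test(expr, labs, fdr = 0.05)
    any(res$significant)
  }, logical(1))
  # family-wise: BH at 5% should flag something in well under a quarter of
  # null relabelings (binomial slack around the nominal rate)
  expect_lt(mean(hits), 0.15)
})
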