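test_that("attention maps are row-stochastic and match the loop oracle", {
  set.seed(31)
  h1 <- matrix(rnorm(12), 4, 3)
  h2 <- matrix(rnorm(15), 5, 3)
  # zero projection -> uniform rows
  expect_equal(attention_cost(h1, h2, matrix(0, 3, 3)),
               matrix(1 / 5, 4, 5))
  # single target column
  expect_equal(attention_cost(h1, h2[1, , drop = FALSE], diag(3)),
               matrix(1, 4, 1))
  for (rep in 1:5) {
    m <- matrix(rnorm(9), 3, 3)
    expect_equal(attention_cost(h1, h2, m),
                 oracle_attention(h1, h2, m, sign = 1), tolerance = 1e-10)
    expect_equal(attention_cost(h1, h2, m, sign = "cost"),
                 oracle_attention(h1, h2, m, sign = -1), tolerance = 1e-10)
  }
  cmat <- attention_cost(h1, h2, matrix(rnorm(9), 3, 3))
  expect_equal(rowSums(cmat), rep(1, 4), tolerance = 1e-6)
  expect_true(all(cmat > 0 & cmat < 1))
})

test_that("Sinkhorn balances marginals and matches an independent solver", {
  u <- matrix(1, 2, 3)
  plan <- sinkhorn_normalize(u)
  expect_equal(plan$pi, matrix(1 / 6, 2, 3), tolerance = 1e-12)
  expect_true(plan$converged)
  expect_lte(plan$iterations, 2L)

  c2 <- rbind(c(2, 1), c(1, 2))
  plan2 <- sinkhorn_normalize(c2, tol = 1e-12)
  expect_equal(plan2$pi, oracle_sinkhorn(c2), tolerance = 1e-10)

  set.seed(32)
  c3 <- matrix(runif(35, 0.2, 3), 5, 7)
  plan3 <- sinkhorn_normalize(c3, tol = 1e-9)
  expect_true(plan3$converged)
  expect_equal(rowSums(plan3$pi), rep(1 / 5, 5), tolerance = 1e-8)
  expect_equal(colSums(plan3$pi), rep(1 / 7, 7), tolerance = 1e-8)
  expect_equal(sum(plan3$pi), 1, tolerance = 1e-9)
  expect_true(all(plan3$pi > 0))
})

test_that("marginal penalty is the closed-form KL to the uniform column law", {
  expect_equal(marginal_penalty(matrix(1 / 6, 2, 3)), 0, tolerance = 1e-12)
  # all mass in column 1 of a 2-column plan: KL = log 2
  p <- cbind(c(0.5, 0.5), c(0, 0))
  expect_equal(marginal_penalty(p), log(2), tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:10) {
    q <- matrix(runif(12), 3, 4)
    q <- q / sum(q)
    expect_gte(marginal_penalty(q), -1e-12)
  }
})

test_that("marginal penalty decreases monotonically over Sinkhorn iterations", {
  set.seed(34)
  cmat <- matrix(runif(30, 0.1, 2), 5, 6)
  sf <- getFromNamespace("sinkhorn_fixed", "jade")
  pens <- vapply(1:8, function(t) marginal_penalty(sf(cmat, t)$pi),
                 numeric(1))
  expect_true(all(diff(pens) <= 1e-12))
  expect_lt(pens[8], pens[1])
})

test_that("maintenance loss vanishes on identity transport and obeys oracle", {
  set.seed(35)
  n <- 5
  d1 <- pairwise_sqdist(matrix(runif(n * 2), n, 2))
  expect_lt(maintain_loss(diag(n) / n, d1, d1), 1e-12)
  d2 <- pairwise_sqdist(matrix(runif(12), 6, 2))
  pi_m <- matrix(runif(30), 5, 6)
  pi_m <- pi_m / sum(pi_m)
  expect_equal(maintain_loss(pi_m, d1, d2), oracle_maintain(pi_m, d1, d2),
               tolerance = 1e-9)
  # simultaneous consistent permutation of both slices
  p1 <- sample(5); p2 <- sample(6)
  expect_equal(maintain_loss(pi_m[p1, p2], d1[p1, p1], d2[p2, p2]),
               maintain_loss(pi_m, d1, d2), tolerance = 1e-12)
})

test_that("permutation plans zero the maintenance loss iff they are isometries", {
  # square grid: a quarter rotation is a distance isometry, a swap of two
  # non-equivalent spots is not
  co <- as.matrix(expand.grid(0:1, 0:1))
  d1 <- pairwise_sqdist(co, mean_normalize = FALSE)
  rot <- c(2, 4, 1, 3)  # 90-degree rotation of the 2x2 grid
  n <- 4
  pi_rot <- diag(n)[rot, ] / n
  expect_lt(maintain_loss(pi_rot, d1, d1), 1e-12)
  # non-isometric permutations on scalene triangle coordinates
  co2 <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 3))
  d3 <- pairwise_sqdist(co2, mean_normalize = FALSE)
  for (perm in list(c(2, 1, 3, 4), c(1, 3, 2, 4), c(4, 2, 3, 1))) {
    pi_p <- diag(4)[perm, ] / 4
    expect_gt(maintain_loss(pi_p, d3, d3), 1e-6)
  }
  expect_lt(maintain_loss(diag(4) / 4, d3, d3), 1e-12)
})

test_that("alignment loss vanishes on identity transport and obeys oracle", {
  set.seed(36)
  n <- 4
  h <- matrix(rnorm(n * 3), n, 3)
  expect_lt(align_loss(diag(n) / n, h, h), 1e-12)
  h1 <- matrix(rnorm(12), 4, 3)
  h2 <- matrix(rnorm(15), 5, 3)
  pi_m <- matrix(runif(20), 4, 5)
  pi_m <- pi_m / sum(pi_m)
  expect_equal(align_loss(pi_m, h1, h2), oracle_align(pi_m, h1, h2),
               tolerance = 1e-10)
  # homogeneity of degree 1
  expect_equal(align_loss(pi_m, 3.5 * h1, 3.5 * h2),
               3.5 * align_loss(pi_m, h1, h2), tolerance = 1e-10)
})
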