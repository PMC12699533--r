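#' Attention-based cross-slice similarity map
#'
#' Projects both slices' embeddings through the learned matrix M and forms
#' row-stochastic attention weights `C = softmax((H1 M)(H2 M)^T / d)`; the
#' logits are scaled by the latent dimension d, with `scale = "sqrt_d"`
#' available for the conventional square-root scaling, and `sign` selecting
#' whether the bilinear form enters as an affinity or as a cost.
#'
#' @param h1 n1 x d embeddings of slice 1.
#' @param h2 n2 x d embeddings of slice 2.
#' @param attn_proj d x d projection matrix M.
#' @param scale `"d"` (default) or `"sqrt_d"`.
#' @param sign `"similarity"` (default) uses the bilinear form as an
#'   affinity: because Sinkhorn normalization is invariant to row and
#'   column factors `exp(-||M^T h||^2 / d)`, the balanced plan equals
#'   entropic optimal transport under the squared Euclidean cost
#'   `||M^T h1_i - M^T h2_j||^2 / d` in the projected space, so mass flows
#'   to matching spots. `"cost"` applies a leading negative sign instead
#'   (the literal cost reading); note that once both slices occupy one
#'   latent space this variant provably concentrates mass on mismatched
#'   pairs (Cauchy-Schwarz), so it is kept only for comparison.
#' @return n1 x n2 row-stochastic matrix with entries in (0, 1).
#' @export
attention_cost <- function(h1, h2, attn_proj, scale = c("d", "sqrt_d"),
                           sign = c("similarity", "cost")) {
  scale <- match.arg(scale)
  sign <- match.arg(sign)
  d <- ncol(h1)
  if (ncol(h2) != d || any(dim(attn_proj) != d))
    stop("latent dimensions of h1, h2 and attn_proj must agree")
  sc <- if (scale == "d") d else sqrt(d)
  sg <- if (sign == "cost") -1 else 1
  logits <- sg * tcrossprod(h1 %*% attn_proj, h2 %*% attn_proj) / sc
  if (!all(is.finite(logits))) stop("non-finite attention logits")
  softmax_rows(logits)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Construct a transport_plan object
#'
#' @param pi nonnegative n1 x n2 matrix of total mass ~1.
#' @param converged logical convergence flag.
#' @param marginal_err max absolute deviation of the row/column sums from the
#'   uniform targets 1/n1 and 1/n2.
#' @param iterations Sinkhorn iterations performed (optional).
#' @return list of class `transport_plan` with `pi`, `n1`, `n2`, `converged`,
#'   `marginal_err`, `iterations`.
#' @export
transport_plan <- function(pi, converged = NA, marginal_err = NA_real_,
                           iterations = NA_integer_) {
  pi <- as.matrix(pi)
  if (any(pi < 0)) stop("transport plan entries must be nonnegative")
  structure(list(pi = pi, n1 = nrow(pi), n2 = ncol(pi),
                 converged = converged, marginal_err = marginal_err,
                 iterations = iterations),
            class = "transport_plan")
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("transport_plan: %d x %d, mass %.6f, marginal_err %.2e (%s)\n",
              x$n1, x$n2, sum(x$pi), x$marginal_err,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

plan_matrix <- function(plan) {
  if (inherits(plan, "transport_plan")) plan$pi else as.matrix(plan)
}

#' Sinkhorn-Knopp normalization to uniform marginals
#'
#' Alternately rescales columns to sum 1/n2 and rows to sum 1/n1, driving a
#' strictly positive similarity map to the doubly-balanced transport plan.
#' Each iteration ends with the row scaling, so row sums are exact and the
#' reported `marginal_err` is the maximal column-sum deviation; the matrix
#' always carries total mass 1 on exit.
#'
#' @param c strictly positive n1 x n2 matrix (e.g. from [attention_cost]).
#' @param max_iters iteration cap (default 200).
#' @param tol convergence tolerance on the marginal error (default 1e-6).
#' @return a [transport_plan].
#' @export
sinkhorn_normalize <- function(c, max_iters = 200L, tol = 1e-6) {
  pi_m <- plan_matrix(c)
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  pi_m[pi_m < 1e-30] <- 1e-30
  err <- Inf
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    pi_m <- sweep(pi_m, 2L, (1 / n2) / colSums(pi_m), "*")
    pi_m <- pi_m * ((1 / n1) / rowSums(pi_m))
    err <- max(abs(colSums(pi_m) - 1 / n2))
    if (err < tol) break
  }
  transport_plan(pi_m, converged = err < tol, marginal_err = err,
                 iterations = it)
}

# fixed-iteration differentiable Sinkhorn used in training: records each
# scaling step so gradients can be pushed back through the recursion
sinkhorn_fixed <- function(c_m, iters) {
  pi_m <- c_m
  pi_m[pi_m < 1e-30] <- 1e-30
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  steps <- vector("list", 2L * iters)
  for (t in seq_len(iters)) {
    s <- colSums(pi_m)
    v <- (1 / n2) / s
    steps[[2L * t - 1L]] <- list(type = "col", pin = pi_m, scale = v)
    pi_m <- sweep(pi_m, 2L, v, "*")
    s <- rowSums(pi_m)
    u <- (1 / n1) / s
    steps[[2L * t]] <- list(type = "row", pin = pi_m, scale = u)
    pi_m <- pi_m * u
  }
  list(pi = pi_m, steps = steps)
}

# reverse-mode pass: d_pi is the gradient at the output; returns the
# gradient with respect to the (clamped) input matrix
sinkhorn_backward <- function(d_pi, steps) {
  n1 <- nrow(d_pi); n2 <- ncol(d_pi)
  for (st in rev(steps)) {
    pin <- st$pin
    v <- st$scale
    if (st$type == "col") {
      dv <- colSums(d_pi * pin)
      ds <- -dv * v^2 * n2       # d s_j: v = (1/n2)/s => dv/ds = -(1/n2)/s^2
      d_pi <- sweep(d_pi, 2L, v, "*") + matrix(ds, n1, n2, byrow = TRUE)
    } else {
      du <- rowSums(d_pi * pin)
      ds <- -du * v^2 * n1
      d_pi <- d_pi * v + matrix(ds, n1, n2)
    }
  }
  d_pi
}

#' Marginal (column-sum) KL penalty
#'
#' KL divergence between the plan's column sums and the uniform target 1/n2,
#' `sum_j c_j log(c_j n2)` with the convention 0 log 0 = 0. Zero exactly when
#' the columns are balanced; strictly positive otherwise. Compensates for
#' the truncated Sinkhorn iterations used during training.
#'
#' @param plan a [transport_plan] or plain matrix.
#' @return nonnegative scalar.
#' @export
marginal_penalty <- function(plan) {
  pi_m <- plan_matrix(plan)
  cs <- colSums(pi_m)
  if (any(cs < 0)) stop("negative column sum in transport plan")
  n2 <- ncol(pi_m)
  pos <- cs > 0
  sum(cs[pos] * log(cs[pos] * n2))
}

#' Spatial-structure maintenance loss
#'
#' `(1/n1) ||D1 - n2^2 Pi D2 Pi^T||_F + (1/n2) ||D2 - n1^2 Pi^T D1 Pi||_F`
#' (unsquared Frobenius norms). The n2^2 / n1^2 factors undo the 1/(n1 n2)
#' mass scale of the plan so the transported distance matrices are
#' commensurate with the originals. Zero iff the plan transports each
#' slice's squared-distance geometry exactly onto the other's.
#'
#' @param plan a [transport_plan] or matrix (n1 x n2).
#' @param sqdist1 n1 x n1 squared-distance matrix of slice 1.
#' @param sqdist2 n2 x n2 squared-distance matrix of slice 2.
#' @return nonnegative scalar.
#' @export
maintain_loss <- function(plan, sqdist1, sqdist2) {
  pi_m <- plan_matrix(plan)
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  if (nrow(sqdist1) != n1 || nrow(sqdist2) != n2)
    stop("distance matrices do not match the plan dimensions")
  r1 <- sqdist1 - n2^2 * (pi_m %*% sqdist2 %*% t(pi_m))
  r2 <- sqdist2 - n1^2 * (t(pi_m) %*% sqdist1 %*% pi_m)
  sqrt(sum(r1^2)) / n1 + sqrt(sum(r2^2)) / n2
}

#' Embedding alignment loss
#'
#' `(1/n1) ||H1 - n2 Pi H2||_F + (1/n2) ||H2 - n1 Pi^T H1||_F` (unsquared
#' norms): each spot's embedding should match the plan-weighted average of
#' its counterparts on the other slice, in both directions.
#'
#' @param plan a [transport_plan] or matrix (n1 x n2).
#' @param h1 n1 x d embeddings.
#' @param h2 n2 x d embeddings.
#' @return nonnegative scalar.
#' @export
align_loss <- function(plan, h1, h2) {
  pi_m <- plan_matrix(plan)
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)
  if (nrow(h1) != n1 || nrow(h2) != n2 || ncol(h1) != ncol(h2))
    stop("embedding shapes do not match the plan")
  sqrt(sum((h1 - n2 * (pi_m %*% h2))^2)) / n1 +
    sqrt(sum((h2 - n1 * (t(pi_m) %*% h1))^2)) / n2
}
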