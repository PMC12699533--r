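#' Loss weights of the joint objective
#'
#' The contrastive term has fixed weight 1; the defaults
#' `lambda2 = 10` (reconstruction), `lambda4 = 0.1` (embedding alignment)
#' and `lambda5 = 1` (marginal penalty) are the method's standard settings.
#' `lambda3` (spatial maintenance) is data-driven by default: see
#' [select_lambda3].
#'
#' @param lambda2,lambda4,lambda5 nonnegative reals.
#' @param lambda3 nonnegative real, or `"auto"` to select from the slices'
#'   pseudo-bulk similarity at training time (range 0.2-2.0).
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(lambda2 = 10, lambda3 = "auto", lambda4 = 0.1,
                         lambda5 = 1) {
  if (!identical(lambda3, "auto")) {
    lambda3 <- as.numeric(lambda3)
    if (lambda3 < 0) stop("lambda3 must be >= 0")
  }
  for (v in c(lambda2, lambda4, lambda5))
    if (!is.finite(v) || v < 0) stop("loss weights must be finite and >= 0")
  structure(list(lambda2 = lambda2, lambda3 = lambda3, lambda4 = lambda4,
                 lambda5 = lambda5), class = "loss_weights")
}

#' Data-driven maintenance weight
#'
#' Measures how similar the two slices are through the Pearson correlation
#' `rho` of their gene-wise mean expression (pseudo-bulk) profiles and maps
#' it linearly onto the prescribed range:
#' `lambda3 = 0.2 + 1.8 * max(rho, 0)`. Similar slices (rho near 1) get a
#' strong spatial-maintenance weight to encourage information sharing;
#' dissimilar slices are down-weighted to prevent negative transfer.
#'
#' @param x1,x2 preprocessed expression matrices over the same gene panel.
#' @return scalar in \[0.2, 2.0\].
#' @export
select_lambda3 <- function(x1, x2) {
  if (ncol(x1) != ncol(x2))
    stop("slices must share the same gene panel")
  pb1 <- colMeans(x1)
  pb2 <- colMeans(x2)
  if (stats::sd(pb1) == 0 || stats::sd(pb2) == 0) {
    warning("zero-variance pseudo-bulk profile; falling back to lambda3 = 0.2")
    return(0.2)
  }
  rho <- stats::cor(pb1, pb2)
  0.2 + 1.8 * max(rho, 0)
}

#' Weighted total training objective
#'
#' `L = L_contrastive + lambda2 L_recon + lambda3 L_maintain +
#'  lambda4 L_align + lambda5 L_marginal`.
#'
#' @param components named numeric vector or list with elements
#'   `contrastive`, `recon`, `maintain`, `align`, `marginal`.
#' @param w a [loss_weights] with a numeric `lambda3`.
#' @return scalar total loss.
#' @export
total_loss <- function(components, w) {
  components <- unlist(components)
  need <- c("contrastive", "recon", "maintain", "align", "marginal")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing loss components: ",
                         paste(miss, collapse = ", "))
  bad <- need[!is.finite(components[need])]
  if (length(bad)) stop("non-finite loss component: ",
                        paste(bad, collapse = ", "))
  if (identical(w$lambda3, "auto"))
    stop("lambda3 is 'auto'; resolve it with select_lambda3() first")
  unname(components["contrastive"] + w$lambda2 * components["recon"] +
           w$lambda3 * components["maintain"] +
           w$lambda4 * components["align"] +
           w$lambda5 * components["marginal"])
}

#' Training configuration
#'
#' @param epochs maximum training epochs (default 500; synthetic presets
#'   converge well before).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed run seed driving initialization, negative sampling and any
#'   k-means; the whole run is deterministic given it.
#' @param sinkhorn_train_iters fixed Sinkhorn iterations differentiated
#'   through during training (default 5; the marginal penalty compensates
#'   for the truncation).
#' @param sinkhorn_eval_iters,sinkhorn_tol inference-time Sinkhorn settings.
#' @param k_neighbors spatial-graph k.
#' @param latent_dim embedding dimension d (default 32).
#' @param early_stop_patience stop when the total loss has not improved for
#'   this many epochs (`Inf` disables; default 50).
#' @param share_encoder constrain the two slices' encoder tensors to stay
#'   equal (one encoder applied to both slices, the standard multi-slice
#'   practice that places both slices in one latent space); `FALSE` trains
#'   fully separate per-slice encoders.
#' @param share_decoder reuse slice-1 decoder weights for slice 2.
#' @param tied_init start both slices' encoder/decoder tensors from the
#'   same draw (see [jade_init_params]); default `TRUE`.
#' @param attn_scale `"d"` or `"sqrt_d"` logit scaling for [attention_cost].
#' @param attn_sign `"cost"` or `"similarity"` (see [attention_cost]).
#' @param roundtrip `"split"` alternates the two phases with gradients
#'   confined to each phase's own parameters; `"joint"` backpropagates the
#'   full objective (including the paths through the attention map and
#'   truncated Sinkhorn plan) into every parameter in one step per epoch.
#' @param verbose print a loss line every 25 epochs.
#' @return list of class `jade_config`.
#' @export
jade_config <- function(epochs = 500L, learning_rate = 1e-3, seed = 0L,
                        sinkhorn_train_iters = 5L,
                        sinkhorn_eval_iters = 200L, sinkhorn_tol = 1e-6,
                        k_neighbors = 6L, latent_dim = 32L,
                        early_stop_patience = 50L, share_encoder = TRUE,
                        share_decoder = FALSE,
                        tied_init = TRUE, attn_scale = "d",
                        attn_sign = "similarity", roundtrip = "split",
                        verbose = FALSE) {
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed),
                 sinkhorn_train_iters = as.integer(sinkhorn_train_iters),
                 sinkhorn_eval_iters = as.integer(sinkhorn_eval_iters),
                 sinkhorn_tol = sinkhorn_tol,
                 k_neighbors = as.integer(k_neighbors),
                 latent_dim = as.integer(latent_dim),
                 early_stop_patience = early_stop_patience,
                 share_encoder = isTRUE(share_encoder),
                 share_decoder = isTRUE(share_decoder),
                 tied_init = isTRUE(tied_init),
                 attn_scale = attn_scale, attn_sign = attn_sign,
                 roundtrip = match.arg(roundtrip, c("split", "joint")),
                 verbose = isTRUE(verbose)),
            class = "jade_config")
}

# ---- Adam -------------------------------------------------------------

adam_new <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(state = state, params = params)
}

# ---- internal forward/backward pieces ---------------------------------

relu_fwd <- function(z) pmax(z, 0)

# norm of a residual matrix and its normalized direction (0 where the norm
# vanishes, so gradients stay finite at the optimum)
.unit_dir <- function(r) {
  nr <- sqrt(sum(r^2))
  if (nr > 0) list(norm = nr, g = r / nr) else list(norm = 0, g = r * 0)
}

# gradients of the truncated-Sinkhorn alignment objective with respect to
# the attention projection M; embeddings (already at the alignment
# resolution) are treated as constants
phase_a_pass <- function(h1, h2, d1, d2, attn_proj, weights, iters,
                         attn_scale, attn_sign = "cost",
                         want_grad = TRUE) {
  d <- ncol(h1)
  sc <- if (attn_scale == "d") d else sqrt(d)
  sg <- if (attn_sign == "cost") -1 else 1
  u1 <- h1 %*% attn_proj
  u2 <- h2 %*% attn_proj
  logits <- sg * tcrossprod(u1, u2) / sc
  cmat <- softmax_rows(logits)
  sk <- sinkhorn_fixed(cmat, iters)
  pi_m <- sk$pi
  n1 <- nrow(pi_m); n2 <- ncol(pi_m)

  r1m <- d1 - n2^2 * (pi_m %*% d2 %*% t(pi_m))
  r2m <- d2 - n1^2 * (t(pi_m) %*% d1 %*% pi_m)
  u1m <- .unit_dir(r1m); u2m <- .unit_dir(r2m)
  maintain <- u1m$norm / n1 + u2m$norm / n2

  r1a <- h1 - n2 * (pi_m %*% h2)
  r2a <- h2 - n1 * (t(pi_m) %*% h1)
  u1a <- .unit_dir(r1a); u2a <- .unit_dir(r2a)
  align <- u1a$norm / n1 + u2a$norm / n2

  cs <- colSums(pi_m)
  marginal <- sum(cs[cs > 0] * log(cs[cs > 0] * n2))

  out <- list(pi = pi_m, maintain = maintain, align = align,
              marginal = marginal)
  if (!want_grad) return(out)

  d_pi <- weights$lambda3 *
    (-(2 * n2^2 / n1) * (u1m$g %*% pi_m %*% d2) -
       (2 * n1^2 / n2) * (d1 %*% pi_m %*% u2m$g)) +
    weights$lambda4 *
    (-(n2 / n1) * tcrossprod(u1a$g, h2) - (n1 / n2) * (h1 %*% t(u2a$g))) +
    weights$lambda5 * matrix(log(pmax(cs, 1e-300) * n2) + 1, n1, n2,
                             byrow = TRUE)
  d_c <- sinkhorn_backward(d_pi, sk$steps)
  # softmax rows backward
  d_logits <- cmat * (d_c - rowSums(d_c * cmat))
  d_u1 <- sg * (d_logits %*% u2) / sc
  d_u2 <- sg * (t(d_logits) %*% u1) / sc
  out$grad_attn <- crossprod(h1, d_u1) + crossprod(h2, d_u2)
  # gradients w.r.t. the embeddings: the path through the attention map and
  # plan, plus the alignment loss's direct dependence (joint mode)
  out$d_h1 <- d_u1 %*% t(attn_proj) +
    weights$lambda4 * (u1a$g / n1 - (n1 / n2) * (pi_m %*% u2a$g))
  out$d_h2 <- d_u2 %*% t(attn_proj) +
    weights$lambda4 * (-(n2 / n1) * (t(pi_m) %*% u1a$g) + u2a$g / n2)
  out
}

# embedding-phase objective (contrastive + weighted reconstruction +
# weighted alignment with the plan fixed) and its gradients with respect to
# the encoder/decoder/discriminator tensors. `env` carries the precomputed
# per-slice constants; `perms` the epoch's negative permutations.
phase_e_pass <- function(params, env, cur_pi, w, perms, want_grad = TRUE,
                         extra_dhh1 = NULL, extra_dhh2 = NULL) {
  n1 <- nrow(env$x1); n2 <- nrow(env$x2)
  d <- ncol(params$enc_weight_1)
  z11 <- sweep(env$ax1 %*% params$enc_weight_1, 2L, params$enc_bias_1, "+")
  z12 <- sweep(env$ax2 %*% params$enc_weight_2, 2L, params$enc_bias_2, "+")
  h1 <- relu_fwd(z11)
  h2 <- relu_fwd(z12)

  grads <- list()
  d_h1 <- matrix(0, n1, d)
  d_h2 <- matrix(0, n2, d)

  # reconstruction
  ah1 <- env$na1 %*% h1
  ah2 <- env$na2 %*% h2
  z21 <- sweep(ah1 %*% params$dec_weight_1, 2L, params$dec_bias_1, "+")
  z22 <- sweep(ah2 %*% params$dec_weight_2, 2L, params$dec_bias_2, "+")
  xh1 <- relu_fwd(z21)
  xh2 <- relu_fwd(z22)
  recon <- sum((env$x1 - xh1)^2) / n1 + sum((env$x2 - xh2)^2) / n2
  if (want_grad) {
    dz21 <- (-(2 / n1) * (env$x1 - xh1)) * (z21 > 0)
    dz22 <- (-(2 / n2) * (env$x2 - xh2)) * (z22 > 0)
    grads$dec_weight_1 <- w$lambda2 * crossprod(ah1, dz21)
    grads$dec_bias_1 <- w$lambda2 * colSums(dz21)
    grads$dec_weight_2 <- w$lambda2 * crossprod(ah2, dz22)
    grads$dec_bias_2 <- w$lambda2 * colSums(dz22)
    d_h1 <- d_h1 + w$lambda2 *
      (env$na1 %*% (dz21 %*% t(params$dec_weight_1)))
    d_h2 <- d_h2 + w$lambda2 *
      (env$na2 %*% (dz22 %*% t(params$dec_weight_2)))
  }

  # contrastive
  phi <- params$disc_weight
  con <- 0
  grads$disc_weight <- matrix(0, d, d)
  for (k in 1:2) {
    h <- if (k == 1) h1 else h2
    p_op <- if (k == 1) env$p1 else env$p2
    nk <- nrow(h)
    perm <- perms[[k]]
    hn <- h[perm, , drop = FALSE]
    r <- p_op %*% h
    rn <- p_op %*% hn
    s_pos <- sigmoid(rowSums((h %*% phi) * r))
    s_neg <- sigmoid(rowSums((hn %*% phi) * rn))
    eps <- 1e-7
    con <- con - mean(log(pmin(pmax(s_pos, eps), 1 - eps))) -
      mean(log(pmin(pmax(1 - s_neg, eps), 1 - eps)))
    if (want_grad) {
      g_pos <- -(1 - s_pos) / nk
      g_neg <- s_neg / nk
      grads$disc_weight <- grads$disc_weight +
        crossprod(h * g_pos, r) + crossprod(hn * g_neg, rn)
      d_h <- g_pos * (r %*% t(phi)) + crossprod(p_op, g_pos * (h %*% phi))
      d_hn <- g_neg * (rn %*% t(phi)) +
        crossprod(p_op, g_neg * (hn %*% phi))
      d_h[perm, ] <- d_h[perm, ] + d_hn
      if (k == 1) d_h1 <- d_h1 + d_h else d_h2 <- d_h2 + d_h
    }
  }

  # alignment at the (possibly coarse) alignment resolution, plan fixed
  hh1 <- if (is.null(env$agg1)) h1 else env$agg1 %*% h1
  hh2 <- if (is.null(env$agg2)) h2 else env$agg2 %*% h2
  m1 <- nrow(hh1); m2 <- nrow(hh2)
  r1a <- hh1 - m2 * (cur_pi %*% hh2)
  r2a <- hh2 - m1 * (t(cur_pi) %*% hh1)
  u1a <- .unit_dir(r1a); u2a <- .unit_dir(r2a)
  align <- u1a$norm / m1 + u2a$norm / m2
  if (want_grad) {
    d_hh1 <- w$lambda4 * (u1a$g / m1 - (m1 / m2) * (cur_pi %*% u2a$g))
    d_hh2 <- w$lambda4 * (-(m2 / m1) * (t(cur_pi) %*% u1a$g) + u2a$g / m2)
    if (!is.null(extra_dhh1)) {
      d_hh1 <- d_hh1 + extra_dhh1
      d_hh2 <- d_hh2 + extra_dhh2
    }
    d_h1 <- d_h1 +
      (if (is.null(env$agg1)) d_hh1 else crossprod(env$agg1, d_hh1))
    d_h2 <- d_h2 +
      (if (is.null(env$agg2)) d_hh2 else crossprod(env$agg2, d_hh2))

    dz11 <- d_h1 * (z11 > 0)
    dz12 <- d_h2 * (z12 > 0)
    grads$enc_weight_1 <- crossprod(env$ax1, dz11)
    grads$enc_bias_1 <- colSums(dz11)
    grads$enc_weight_2 <- crossprod(env$ax2, dz12)
    grads$enc_bias_2 <- colSums(dz12)
  }
  list(recon = recon, contrastive = con, align = align, grads = grads,
       h1 = h1, h2 = h2)
}

# sum the two slices' gradients into the slice-1 tensors when encoder or
# decoder weights are shared, zeroing the slice-2 copies
tie_shared_grads <- function(grads, config) {
  if (config$share_encoder) {
    grads$enc_weight_1 <- grads$enc_weight_1 + grads$enc_weight_2
    grads$enc_bias_1 <- grads$enc_bias_1 + grads$enc_bias_2
    grads$enc_weight_2 <- grads$enc_weight_1 * 0
    grads$enc_bias_2 <- grads$enc_bias_1 * 0
  }
  if (config$share_decoder) {
    grads$dec_weight_1 <- grads$dec_weight_1 + grads$dec_weight_2
    grads$dec_bias_1 <- grads$dec_bias_1 + grads$dec_bias_2
    grads$dec_weight_2 <- grads$dec_weight_1 * 0
    grads$dec_bias_2 <- grads$dec_bias_1 * 0
  }
  grads
}

copy_shared_params <- function(params, config) {
  if (config$share_encoder) {
    params$enc_weight_2 <- params$enc_weight_1
    params$enc_bias_2 <- params$enc_bias_1
  }
  if (config$share_decoder) {
    params$dec_weight_2 <- params$dec_weight_1
    params$dec_bias_2 <- params$dec_bias_1
  }
  params
}

# ---- the roundtrip training loop --------------------------------------

#' Train the joint alignment-and-embedding model on a slice pair
#'
#' Runs the roundtrip optimization: each epoch first refines the per-slice
#' encoders/decoders and the contrastive discriminator on the contrastive +
#' reconstruction + alignment objective with the transport plan held fixed
#' (embedding phase), then recomputes the attention map and truncated
#' Sinkhorn plan and refines the attention projection on the maintenance +
#' alignment + marginal objective with the embeddings held fixed (alignment
#' phase). With `fast = TRUE` the attention/transport computations run at
#' hyperspot resolution (see [build_hyperspots]) and the final plan is
#' recovered at full resolution with the trained projection.
#'
#' @param a,b preprocessed [slice_data] objects sharing an identical gene
#'   panel (see [preprocess_pair]).
#' @param config a [jade_config].
#' @param weights a [loss_weights]; `lambda3 = "auto"` resolves via
#'   [select_lambda3].
#' @param fast coarsen the alignment computations to hyperspots.
#' @param hyperspot_fraction hyperspots per spot (default 0.15, i.e. the
#'   10-20 percent regime); `1` uses the degenerate identity partition,
#'   which reproduces the full-resolution model exactly.
#' @return An object of class `jade_result`: `embeddings` (list `h1`, `h2`),
#'   `plan` (fully converged inference-time [transport_plan]),
#'   `loss_history` (one row per epoch), `weights`, `params`, `graphs`,
#'   `partitions` (fast mode), `seed`, `config`.
#' @export
train_jade <- function(a, b, config = jade_config(), weights = loss_weights(),
                       fast = FALSE, hyperspot_fraction = 0.15) {
  stopifnot(inherits(a, "slice_data"), inherits(b, "slice_data"))
  if (!identical(a$gene_ids, b$gene_ids))
    stop("slices must be preprocessed to an identical shared gene panel")
  w <- weights
  if (identical(w$lambda3, "auto")) w$lambda3 <- select_lambda3(a$expr, b$expr)

  g1 <- spatial_graph(a$coords, k = config$k_neighbors)
  g2 <- spatial_graph(b$coords, k = config$k_neighbors)
  p <- a$p
  d <- config$latent_dim
  params <- jade_init_params(p, d, seed = config$seed,
                             share_decoder = config$share_decoder,
                             tied_init = config$tied_init)

  # hyperspot partitions (fast mode); fraction 1 = identity partition, a
  # code path identical to full resolution
  parts <- NULL
  agg1 <- agg2 <- NULL
  d1c <- g1$sqdist
  d2c <- g2$sqdist
  if (fast) {
    if (hyperspot_fraction >= 1) {
      parts <- list(hyperspot_identity_partition(a$coords),
                    hyperspot_identity_partition(b$coords))
    } else {
      parts <- list(
        build_hyperspots(a$coords, hyperspot_fraction, config$seed + 1L),
        build_hyperspots(b$coords, hyperspot_fraction, config$seed + 1L))
      agg1 <- aggregation_operator(parts[[1]])
      agg2 <- aggregation_operator(parts[[2]])
      d1c <- pairwise_sqdist(parts[[1]]$centroid_coords)
      d2c <- pairwise_sqdist(parts[[2]]$centroid_coords)
    }
  }

  x1 <- a$expr; x2 <- b$expr
  n1 <- a$n; n2 <- b$n
  ax1 <- g1$norm_adj %*% x1
  ax2 <- g2$norm_adj %*% x2
  p1_op <- proxy_operator(g1$neighbor_sets, n1)
  p2_op <- proxy_operator(g2$neighbor_sets, n2)

  enc_names <- c("enc_weight_1", "enc_bias_1", "enc_weight_2", "enc_bias_2",
                 "dec_weight_1", "dec_bias_1", "dec_weight_2", "dec_bias_2",
                 "disc_weight")
  env <- list(x1 = x1, x2 = x2, ax1 = ax1, ax2 = ax2,
              na1 = g1$norm_adj, na2 = g2$norm_adj,
              p1 = p1_op, p2 = p2_op, agg1 = agg1, agg2 = agg2)
  opt_e <- adam_new()
  opt_a <- adam_new()
  hist <- vector("list", config$epochs)
  cur_pi <- NULL
  best_total <- Inf
  since_best <- 0L
  n_done <- 0L

  forward_slice <- function(x, ax, g, wname, bname) {
    z <- sweep(ax %*% params[[wname]], 2L, params[[bname]], "+")
    h <- relu_fwd(z)
    list(z = z, h = h)
  }

  withr::with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      perms <- list(sample.int(n1), sample.int(n2))
      if (config$roundtrip == "split") {
        ## ---- phase E: encoders/decoders/discriminator, plan fixed ----
        if (is.null(cur_pi)) {
          f1 <- forward_slice(x1, ax1, g1, "enc_weight_1", "enc_bias_1")
          f2 <- forward_slice(x2, ax2, g2, "enc_weight_2", "enc_bias_2")
          hh1 <- if (is.null(agg1)) f1$h else agg1 %*% f1$h
          hh2 <- if (is.null(agg2)) f2$h else agg2 %*% f2$h
          cur_pi <- phase_a_pass(hh1, hh2, d1c, d2c, params$attn_proj, w,
                                 config$sinkhorn_train_iters,
                                 config$attn_scale, config$attn_sign,
                                 want_grad = FALSE)$pi
        }
        pe <- phase_e_pass(params, env, cur_pi, w, perms)
        recon <- pe$recon
        con <- pe$contrastive
        grads <- pe$grads

        grads <- tie_shared_grads(grads, config)
        st <- adam_step(opt_e, params, grads[enc_names],
                        config$learning_rate)
        opt_e <- st$state
        params <- copy_shared_params(st$params, config)

        ## ---- phase A: attention projection, embeddings fixed ----
        f1 <- forward_slice(x1, ax1, g1, "enc_weight_1", "enc_bias_1")
        f2 <- forward_slice(x2, ax2, g2, "enc_weight_2", "enc_bias_2")
        hh1 <- if (is.null(agg1)) f1$h else agg1 %*% f1$h
        hh2 <- if (is.null(agg2)) f2$h else agg2 %*% f2$h
        pa <- phase_a_pass(hh1, hh2, d1c, d2c, params$attn_proj, w,
                           config$sinkhorn_train_iters, config$attn_scale,
                           config$attn_sign)
        st <- adam_step(opt_a, params["attn_proj"],
                        list(attn_proj = pa$grad_attn),
                        config$learning_rate)
        opt_a <- st$state
        params$attn_proj <- st$params$attn_proj

        # refreshed plan for the next embedding phase
        cur_pi <- phase_a_pass(hh1, hh2, d1c, d2c, params$attn_proj, w,
                               config$sinkhorn_train_iters,
                               config$attn_scale, config$attn_sign,
                               want_grad = FALSE)$pi
      } else {
        ## ---- joint: one backward pass through the whole objective ----
        f1 <- forward_slice(x1, ax1, g1, "enc_weight_1", "enc_bias_1")
        f2 <- forward_slice(x2, ax2, g2, "enc_weight_2", "enc_bias_2")
        hh1 <- if (is.null(agg1)) f1$h else agg1 %*% f1$h
        hh2 <- if (is.null(agg2)) f2$h else agg2 %*% f2$h
        pa <- phase_a_pass(hh1, hh2, d1c, d2c, params$attn_proj, w,
                           config$sinkhorn_train_iters, config$attn_scale,
                           config$attn_sign)
        w0 <- w
        w0$lambda4 <- 0  # alignment gradients arrive via pa$d_h*
        pe <- phase_e_pass(params, env, pa$pi, w0, perms,
                           extra_dhh1 = pa$d_h1, extra_dhh2 = pa$d_h2)
        recon <- pe$recon
        con <- pe$contrastive
        grads <- pe$grads
        grads$attn_proj <- pa$grad_attn
        grads <- tie_shared_grads(grads, config)
        st <- adam_step(opt_e, params,
                        grads[c(enc_names, "attn_proj")],
                        config$learning_rate)
        opt_e <- st$state
        params <- copy_shared_params(st$params, config)
      }

      comp <- c(contrastive = con, recon = recon, maintain = pa$maintain,
                align = pa$align, marginal = max(pa$marginal, 0))
      tot <- total_loss(comp, w)
      if (!is.finite(tot))
        stop("training diverged at epoch ", epoch, "; components: ",
             paste(names(comp), signif(unlist(comp), 4), sep = "=",
                   collapse = ", "))
      hist[[epoch]] <- c(epoch = epoch, comp, total = tot)
      n_done <- epoch
      if (config$verbose && (epoch %% 25L == 0L || epoch == 1L))
        message(sprintf("epoch %4d  total %.4f", epoch, tot))

      if (tot < best_total - 1e-12) {
        best_total <- tot
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$early_stop_patience) break
      }
    }
  })

  # inference: final embeddings and a fully converged full-resolution plan
  f1 <- forward_slice(x1, ax1, g1, "enc_weight_1", "enc_bias_1")
  f2 <- forward_slice(x2, ax2, g2, "enc_weight_2", "enc_bias_2")
  cmat <- attention_cost(f1$h, f2$h, params$attn_proj,
                         scale = config$attn_scale,
                         sign = config$attn_sign)
  plan <- sinkhorn_normalize(cmat, max_iters = config$sinkhorn_eval_iters,
                             tol = config$sinkhorn_tol)
  rownames(plan$pi) <- a$spot_ids
  colnames(plan$pi) <- b$spot_ids
  lh <- as.data.frame(do.call(rbind, hist[seq_len(n_done)]))
  structure(
    list(embeddings = list(h1 = f1$h, h2 = f2$h), plan = plan,
         loss_history = lh, weights = w, params = params,
         graphs = list(g1 = g1, g2 = g2), partitions = parts,
         seed = config$seed, config = config),
    class = "jade_result")
}

#' @export
print.jade_result <- function(x, ...) {
  cat(sprintf(
    "jade_result: %d x %d plan (marginal_err %.2e), d = %d, %d epochs, final total loss %.4f\n",
    x$plan$n1, x$plan$n2, x$plan$marginal_err, ncol(x$embeddings$h1),
    nrow(x$loss_history), x$loss_history$total[nrow(x$loss_history)]))
  invisible(x)
}
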