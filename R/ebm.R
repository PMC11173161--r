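# Energy-based regression in logit space. A fully connected energy net
# scores the compatibility of (global graph embedding X, candidate logit
# y); training uses a noise-contrastive objective against adversarial
# logits drawn from a sliding-width normal proposal; inference is a
# brute-force scan over an even grid of scores in (0,1).
#
# Sign convention: the net outputs an energy E (lower = more compatible).
# The contrastive objective is computed on f = -E, so minimising the loss
# pushes the true target's energy down relative to the adversarial ones,
# and grid inference returns the score of minimal energy.

#' Energy-based model configuration
#'
#' @param M total samples per example in the contrastive objective,
#'   including the (noised) true target; `M - 1` are adversarial. M >= 2.
#' @param beta noise intensity on the true target (variance multiplier
#'   `beta * sigma^2` in logit space)
#' @param gamma quartile distance of the proposal in (0,1) score space;
#'   determines the sliding proposal width via [sliding_sigma()]
#' @param K number of proposal mixture components (held fixed at 1)
#' @param grid_n number of evenly spaced scores scanned at inference
#' @param eps_clamp scores are clamped to `[eps, 1-eps]` before the logit
#' @param skip_depth number of hidden layers (after the first) that
#'   re-concatenate the input logit (skip connections)
#' @param hidden integer vector of hidden layer widths
#' @param use_norm apply layer normalisation after hidden activations
#' @param dropout dropout rate during training
#' @return an `EBMConfig` list
#' @export
ebm_config <- function(M = 65L, beta = 0.05, gamma = 0.1, K = 1L,
                       grid_n = 1000L, eps_clamp = 1e-6, skip_depth = 2L,
                       hidden = c(32L, 32L), use_norm = FALSE,
                       dropout = 0) {
  stopifnot(M >= 2L, beta > 0, gamma > 0, gamma < 1, K == 1L,
            grid_n >= 2L, eps_clamp > 0, eps_clamp < 0.5,
            skip_depth >= 0L, length(hidden) >= 1L)
  structure(list(M = as.integer(M), beta = beta, gamma = gamma, K = 1L,
                 grid_n = as.integer(grid_n), eps_clamp = eps_clamp,
                 skip_depth = as.integer(skip_depth),
                 hidden = as.integer(hidden), use_norm = use_norm,
                 dropout = dropout),
            class = "EBMConfig")
}

#' Logit and sigmoid between score space (0,1) and the real line
#'
#' Scores are clamped to `[eps, 1-eps]` before the logit so the transform
#' is always finite; the pair is an exact inverse inside the clamp range.
#'
#' @param p scores in (0,1) (vectorised)
#' @param y logits (vectorised)
#' @param eps clamp width
#' @return transformed values
#' @export
logit_score <- function(p, eps = 1e-6) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' @rdname logit_score
#' @export
sigmoid_score <- function(y) stats::plogis(y)

#' Standard-normal third-quartile z value
#'
#' The constant that converts a quartile distance into a standard
#' deviation: the 75th-percentile z of the standard normal, approximately
#' 0.675.
#'
#' @return `qnorm(0.75)`
#' @export
quartile_z <- function() stats::qnorm(0.75)

#' Sliding proposal standard deviation in logit space
#'
#' Chooses sigma so that the proposal's quartiles, mapped back to (0,1),
#' sit approximately `gamma` away from the true score `mu`:
#' `sigma = (logit(mu + gamma) - logit(mu)) / z` when `mu + gamma < 1`,
#' else the mirrored lower branch. `z` is the standard-normal
#' third-quartile value (~0.675). This keeps the proposal roughly equally
#' wide in score space for all `mu`, compensating for the logit's
#' asymptotes.
#'
#' @param mu true score(s) in (0,1)
#' @param gamma quartile distance in (0,1)
#' @param eps clamp width applied before each logit
#' @param z quartile constant (default [quartile_z()])
#' @return sigma > 0 (vectorised over `mu`)
#' @export
sliding_sigma <- function(mu, gamma, eps = 1e-6, z = quartile_z()) {
  stopifnot(gamma > 0, gamma < 1)
  upper <- (logit_score(mu + gamma, eps) - logit_score(mu, eps)) / z
  lower <- (logit_score(mu, eps) - logit_score(mu - gamma, eps)) / z
  out <- ifelse(mu + gamma < 1, upper, lower)
  stopifnot(all(out > 0))
  out
}

#' Sample contrastive targets for one true score
#'
#' All sampling happens in logit space around `logit(y)`. The noised true
#' target adds noise of variance `beta * sigma^2`; the `M - 1` adversarial
#' targets are drawn from `N(logit(y), sigma^2)` with sigma from
#' [sliding_sigma()]. Every sample carries its log density under the
#' adversarial proposal (the correction term in the contrastive loss).
#'
#' @param y_score true score in (0,1)
#' @param cfg an [ebm_config()]
#' @return list with `y0` (list: `value`, `log_density`) and
#'   `adversarial` (list of `M - 1` such samples)
#' @export
sample_targets <- function(y_score, cfg) {
  sm <- sample_targets_matrix(y_score, cfg)
  samples <- lapply(seq_len(cfg$M), function(m) {
    list(value = sm$values[1L, m], log_density = sm$log_density[1L, m])
  })
  list(y0 = samples[[1L]], adversarial = samples[-1L])
}

# Vectorised sampler: values and proposal log-densities as B x M matrices,
# column 1 = noised true target.
sample_targets_matrix <- function(y_scores, cfg) {
  B <- length(y_scores)
  mu <- logit_score(y_scores, cfg$eps_clamp)
  sigma <- sliding_sigma(y_scores, cfg$gamma, cfg$eps_clamp)
  vals <- matrix(0, B, cfg$M)
  vals[, 1L] <- mu + stats::rnorm(B, 0, sqrt(cfg$beta) * sigma)
  vals[, -1L] <- mu + stats::rnorm(B * (cfg$M - 1L), 0, sigma)
  ld <- stats::dnorm(vals, mean = mu, sd = sigma, log = TRUE)
  list(values = vals, log_density = ld, mu = mu, sigma = sigma)
}

#' Noise-contrastive loss for energy-based regression
#'
#' Given per-sample scores `f = -energy` and matching proposal
#' log-densities (column 1 = the noised true target), the loss is the
#' negative mean log probability of picking the true column under the
#' density-corrected softmax:
#' `J = -mean_i log[ exp(f_i0 - logP_i0) / sum_m exp(f_im - logP_im) ]`,
#' computed with a numerically stable log-sum-exp.
#'
#' @param scores n x M matrix of `-energy` values
#' @param log_densities n x M matrix of proposal log densities
#' @return scalar loss, always >= 0
#' @export
nce_loss <- function(scores, log_densities) {
  scores <- as.matrix(scores); log_densities <- as.matrix(log_densities)
  stopifnot(identical(dim(scores), dim(log_densities)), ncol(scores) >= 2L)
  if (!all(is.finite(scores))) stop("non-finite energy in nce_loss")
  a <- scores - log_densities
  mx <- apply(a, 1L, max)
  lse <- mx + log(rowSums(exp(a - mx)))
  -mean(a[, 1L] - lse)
}

## ---- energy network ------------------------------------------------------

# Layer input widths given embedding width and config.
ebm_layer_sizes <- function(cfg, embed_dim) {
  H <- length(cfg$hidden)
  ins <- integer(H + 1L)
  outs <- c(cfg$hidden, 1L)
  ins[1L] <- embed_dim + 1L
  for (l in seq_len(H)) {
    ins[l + 1L] <- cfg$hidden[l] + if (l <= cfg$skip_depth) 1L else 0L
  }
  list(ins = ins, outs = outs)
}

#' Initialise an energy network
#'
#' A fully connected stack on the concatenated (embedding, logit) input;
#' each hidden layer is followed by dropout (training only), ReLU, and a
#' skip connection re-concatenating the input logit for the first
#' `skip_depth` hidden layers.
#'
#' @param cfg an [ebm_config()]
#' @param embed_dim width of the global embedding consumed
#' @param seed RNG seed for initialisation
#' @return a `meqa_ebm` object
#' @export
new_ebm <- function(cfg, embed_dim, seed = 1L) {
  set.seed(seed)
  sz <- ebm_layer_sizes(cfg, embed_dim)
  params <- list()
  for (l in seq_along(sz$ins)) {
    params <- c(params, nn_init_linear(sz$ins[l], sz$outs[l],
                                       paste0("e_l", l)))
  }
  structure(list(cfg = cfg, params = params, embed_dim = embed_dim,
                 log = NULL),
            class = "meqa_ebm")
}

# Tape forward: X (B x w), y (B x 1 logits) -> energy node id (B x 1).
ebm_fwd <- function(tape, ids, cfg, Xv, yv, dropout = 0) {
  X <- ad_leaf(tape, Xv)
  y <- ad_leaf(tape, yv)
  h <- ad_cbind(tape, X, y)
  H <- length(cfg$hidden)
  for (l in seq_len(H)) {
    h <- nn_linear(tape, h, ids, "e", l)
    h <- nn_dropout(tape, h, dropout)
    h <- ad_relu(tape, h)
    if (cfg$use_norm) h <- nn_layernorm(tape, h)
    if (l <= cfg$skip_depth) h <- ad_cbind(tape, h, y)
  }
  nn_linear(tape, h, ids, "e", H + 1L)
}

#' Evaluate the energy of (embedding, logit) pairs
#'
#' Deterministic (no dropout).
#'
#' @param net a `meqa_ebm`
#' @param X embedding matrix (B x embed_dim) or a single vector
#' @param y logit values (length B)
#' @return numeric vector of energies
#' @export
ebm_energy <- function(net, X, y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == net$embed_dim)
  if (nrow(X) == 1L && length(y) > 1L) {
    X <- X[rep(1L, length(y)), , drop = FALSE]
  }
  stopifnot(nrow(X) == length(y))
  tape <- ad_tape()
  ids <- ad_params(tape, net$params)
  out <- ebm_fwd(tape, ids, net$cfg, X, matrix(y, ncol = 1L))
  ad_value(tape, out)[, 1L]
}

#' Brute-force grid inference
#'
#' Evaluates the energy at the logits of `grid_n` evenly spaced scores
#' `(k - 0.5)/grid_n` and returns the score with minimal energy (ties:
#' smallest score).
#'
#' @param net a `meqa_ebm`
#' @param X one embedding (vector or 1 x embed_dim matrix)
#' @param grid_n grid resolution (default: from the net's config)
#' @return predicted score in (0,1)
#' @export
grid_inference <- function(net, X, grid_n = net$cfg$grid_n) {
  stopifnot(grid_n >= 2L)
  s <- (seq_len(grid_n) - 0.5) / grid_n
  e <- ebm_energy(net, X, logit_score(s, net$cfg$eps_clamp))
  s[which.min(e)]
}

#' Train an energy-based regressor with the contrastive objective
#'
#' @param net a `meqa_ebm`
#' @param X embedding matrix (n x embed_dim)
#' @param scores true quality scores in (0,1), length n
#' @param epochs training epochs
#' @param batch minibatch size (examples; each contributes M samples)
#' @param lr Adam learning rate
#' @param val_idx held-out indices monitored by grid-inference MAE
#'   (default: every tenth example); a coarse grid is used during
#'   monitoring for speed
#' @param clip_percentile AutoClip percentile
#' @param seed RNG seed (data order, target sampling, dropout)
#' @param verbose print per-epoch losses
#' @return the trained `meqa_ebm`; `$log` holds epoch, train_loss, val_mae
#' @export
train_ebm <- function(net, X, scores, epochs = 30L, batch = 32L,
                      lr = 1e-3, val_idx = NULL, clip_percentile = 10,
                      seed = 1L, verbose = FALSE) {
  stopifnot(nrow(X) == length(scores), all(scores > 0), all(scores < 1))
  set.seed(seed)
  cfg <- net$cfg
  if (is.null(val_idx)) {
    val_idx <- if (nrow(X) >= 10L) seq(10L, nrow(X), by = 10L) else
      nrow(X)
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  params <- net$params
  state <- nn_adam_state(params)
  history <- numeric(0)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_mae = numeric(0))
  M <- cfg$M
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / batch))
    tls <- numeric(0)
    for (bi in batches) {
      B <- length(bi)
      sm <- sample_targets_matrix(scores[bi], cfg)
      # flat order: example 1's M samples first (column-major reshape
      # with nrow = M recovers one example per column)
      yflat <- matrix(as.vector(t(sm$values)), ncol = 1L)
      ldflat <- as.vector(t(sm$log_density))
      Xrep <- X[rep(bi, each = M), , drop = FALSE]
      tape <- ad_tape()
      ids <- ad_params(tape, params)
      energy <- ebm_fwd(tape, ids, cfg, Xrep, yflat,
                        dropout = cfg$dropout)
      f <- ad_scale(tape, energy, -1)
      a <- ad_sub(tape, f, ad_leaf(tape, matrix(ldflat, ncol = 1L)))
      A <- ad_reshape(tape, a, M, B)
      Av <- ad_value(tape, A)
      shift <- matrix(apply(Av, 2L, max), M, B, byrow = TRUE)
      ex <- ad_exp(tape, ad_sub(tape, A, ad_leaf(tape, shift)))
      csum <- ad_matmul(tape, ad_leaf(tape, matrix(1, 1L, M)), ex)
      lse <- ad_add(tape, ad_log(tape, csum),
                    ad_leaf(tape, shift[1L, , drop = FALSE]))
      a_true <- ad_gather(tape, a, (seq_len(B) - 1L) * M + 1L)
      J <- ad_scale(tape, ad_sum(tape, ad_sub(tape,
             ad_transpose(tape, lse), a_true)), 1 / B)
      grads <- ad_backward(tape, J)
      g <- ad_param_grads(tape, grads, ids, params)
      nrm <- nn_grad_norm(g)
      ac <- autoclip_step(history, nrm, clip_percentile)
      history <- ac$history
      g <- nn_clip_grads(g, nrm, ac$threshold)
      st <- nn_adam_step(params, g, state, lr = lr)
      params <- st$params; state <- st$state
      tls <- c(tls, ad_value(tape, J)[1L, 1L])
    }
    net$params <- params
    vidx <- if (length(val_idx) > 50L) val_idx[seq_len(50L)] else val_idx
    vm <- mean(vapply(vidx, function(i) {
      abs(grid_inference(net, X[i, ], grid_n = 200L) - scores[i])
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tls),
                                 val_mae = vm))
    if (verbose) {
      message(sprintf("epoch %d: J %.4f val MAE %.4f", ep, mean(tls), vm))
    }
  }
  net$params <- params
  net$log <- log
  net
}
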