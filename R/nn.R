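# Shared neural-network building blocks: initialisation, MLP forward on an
# autodiff tape, Adam, adaptive gradient clipping (AutoClip), dropout and
# layer normalisation. Used by both the graph backbones and the energy net.

# Kaiming-style init for a d_in x d_out weight matrix.
nn_init_linear <- function(d_in, d_out, prefix) {
  w <- matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
  b <- matrix(0, 1L, d_out)
  stats::setNames(list(w, b), paste0(prefix, c("_w", "_b")))
}

# params for an MLP with layer sizes `sizes` (input first, output last).
nn_init_mlp <- function(sizes, prefix) {
  out <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    out <- c(out, nn_init_linear(sizes[l], sizes[l + 1L],
                                 paste0(prefix, "_l", l)))
  }
  out
}

nn_linear <- function(tape, x, ids, prefix, layer) {
  h <- ad_matmul(tape, x, ids[[paste0(prefix, "_l", layer, "_w")]])
  ad_add_bias(tape, h, ids[[paste0(prefix, "_l", layer, "_b")]])
}

# MLP forward: ReLU between layers, linear last layer. `n_layers` counts
# weight matrices. Optional layer norm after each hidden activation.
nn_mlp <- function(tape, x, ids, prefix, n_layers, use_norm = FALSE) {
  h <- x
  for (l in seq_len(n_layers)) {
    h <- nn_linear(tape, h, ids, prefix, l)
    if (l < n_layers) {
      h <- ad_relu(tape, h)
      if (use_norm) h <- nn_layernorm(tape, h)
    }
  }
  h
}

# Parameter-free layer normalisation over each row, composed from autodiff
# primitives (broadcasts via matmul with constant one-vectors).
nn_layernorm <- function(tape, x, eps = 1e-5) {
  d <- ncol(ad_value(tape, x))
  ones_col <- ad_leaf(tape, matrix(1 / d, d, 1L))   # row mean projector
  ones_row <- ad_leaf(tape, matrix(1, 1L, d))
  mu <- ad_matmul(tape, x, ones_col)                # n x 1
  xc <- ad_sub(tape, x, ad_matmul(tape, mu, ones_row))
  v <- ad_matmul(tape, ad_mul(tape, xc, xc), ones_col)
  sd_ <- ad_sqrt(tape, ad_push(tape, ad_value(tape, v) + eps, v,
                               function(g) list(g)))
  ad_div(tape, xc, ad_matmul(tape, sd_, ones_row))
}

# Inverted dropout: active only when a rate > 0 is given; the caller
# controls the RNG stream. Identity at rate 0 (evaluation mode).
nn_dropout <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  V <- ad_value(tape, x)
  mask <- matrix(stats::rbinom(length(V), 1L, 1 - rate) / (1 - rate),
                 nrow(V), ncol(V))
  ad_mul(tape, x, ad_leaf(tape, mask))
}

## ---- optimiser -----------------------------------------------------------

nn_adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- AutoClip ------------------------------------------------------------

#' Adaptive gradient clipping threshold (AutoClip)
#'
#' Maintains the history of observed gradient norms and clips each new
#' gradient to the given percentile of the history (which includes the new
#' norm). With an empty history the threshold equals the incoming norm, so
#' the first step is never clipped.
#'
#' @param history numeric vector of previously observed global grad norms
#' @param new_norm the current gradient norm
#' @param percentile percentile in (0, 100] (default 10)
#' @return list with `threshold` (clip value, linear-interpolation
#'   percentile) and `history` (updated history vector)
#' @export
autoclip_step <- function(history, new_norm, percentile = 10) {
  stopifnot(percentile > 0, percentile <= 100, new_norm >= 0)
  history <- c(history, new_norm)
  thr <- unname(stats::quantile(history, percentile / 100))
  list(threshold = thr, history = history)
}

# Flattened L2 norm over a parameter-gradient list.
nn_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
}

nn_clip_grads <- function(grads, norm, threshold) {
  if (norm > threshold && norm > 0) {
    grads <- lapply(grads, function(g) g * (threshold / norm))
  }
  grads
}

#' Weighted L1 loss
#'
#' `sum(w * |pred - true|) / sum(w)`. With unit weights this is the mean
#' absolute error. Used for backbone pretraining where weights correct for
#' skew in the quality-score distribution.
#'
#' @param pred,true numeric vectors of equal length
#' @param weights non-negative weights, not all zero
#' @return scalar loss
#' @export
weighted_l1_loss <- function(pred, true, weights = rep(1, length(pred))) {
  stopifnot(length(pred) == length(true), length(weights) == length(pred))
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) stop("at least one weight must be positive")
  sum(weights * abs(pred - true)) / sw
}

# Inverse-frequency weights over `bins` equal-width bins of scores in [0,1].
nn_inverse_frequency_weights <- function(scores, bins = 10L) {
  b <- pmin(pmax(ceiling(scores * bins), 1L), bins)
  counts <- tabulate(b, nbins = bins)
  w <- 1 / counts[b]
  w / mean(w)
}
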