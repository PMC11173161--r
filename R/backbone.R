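# Graph regression backbones. Two variants: a graph transformer
# (multi-head attention over contact-graph neighbourhoods with edge
# features injected into keys and values, each layer followed by TopK
# pooling) and a MetaLayer-style block (separate edge, node and global
# update networks). Both end in global attention pooling producing the
# global embedding X, and a fully connected head squashing X to a quality
# score in (0,1). Trained with weighted L1, Adam and AutoClip.

#' Backbone configuration
#'
#' @param variant `"transformer"` or `"metalayer"`
#' @param n_layers number of GNN layers (>= 1)
#' @param hidden hidden width (divisible by `heads` for the transformer)
#' @param heads attention heads (transformer variant)
#' @param topk_ratio fraction of nodes kept by TopK pooling after each
#'   transformer layer, in (0, 1]; gating applies even at ratio 1
#' @param use_norm apply layer normalisation after each GNN layer
#' @param score_type which quality score this backbone predicts:
#'   `"fold"` (overall fold) or `"interface"`
#' @param dropout dropout rate used during training (0 at evaluation)
#' @return a `BackboneConfig` list
#' @export
backbone_config <- function(variant = c("transformer", "metalayer"),
                            n_layers = 2L, hidden = 16L, heads = 2L,
                            topk_ratio = 0.8, use_norm = FALSE,
                            score_type = c("fold", "interface"),
                            dropout = 0) {
  variant <- match.arg(variant)
  score_type <- match.arg(score_type)
  stopifnot(n_layers >= 1L, hidden >= 1L, topk_ratio > 0, topk_ratio <= 1)
  if (variant == "transformer" && hidden %% heads != 0L) {
    stop("hidden width must be divisible by the number of heads")
  }
  structure(list(variant = variant, n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden), heads = as.integer(heads),
                 topk_ratio = topk_ratio, use_norm = use_norm,
                 score_type = score_type, dropout = dropout),
            class = "BackboneConfig")
}

#' Package a graph and its feature matrices for the backbone
#'
#' Converts an undirected `ResidueGraph` plus node/edge feature matrices
#' into the directed form message passing consumes (each undirected edge
#' becomes two directed edges carrying the same feature row).
#'
#' @param g a `ResidueGraph`
#' @param node_x node feature matrix (n x F)
#' @param edge_x edge feature matrix (edges x 10)
#' @return list with `node_x`, `src`, `dst`, `edge_x` (directed), `n`
#' @export
graph_input <- function(g, node_x, edge_x) {
  stopifnot(nrow(node_x) == length(g$nodes))
  e <- g$edges
  if (nrow(e)) {
    src <- c(e[, 1], e[, 2])
    dst <- c(e[, 2], e[, 1])
    ex <- rbind(edge_x, edge_x)
  } else {
    src <- integer(0); dst <- integer(0)
    ex <- matrix(0, 0L, ncol(edge_x))
  }
  list(node_x = as.matrix(node_x), src = src, dst = dst,
       edge_x = as.matrix(ex), n = length(g$nodes))
}

## ---- initialisation ------------------------------------------------------

backbone_init <- function(config, node_dim, edge_dim = 10L, seed = 1L) {
  set.seed(seed)
  h <- config$hidden
  p <- list()
  if (config$variant == "transformer") {
    dh <- h %/% config$heads
    for (l in seq_len(config$n_layers)) {
      d_in <- if (l == 1L) node_dim else h
      pref <- paste0("t", l)
      for (hd in seq_len(config$heads)) {
        hp <- paste0(pref, "_h", hd)
        p[[paste0(hp, "_wq")]] <- matrix(stats::rnorm(d_in * dh,
          sd = sqrt(1 / d_in)), d_in, dh)
        p[[paste0(hp, "_wk")]] <- matrix(stats::rnorm(d_in * dh,
          sd = sqrt(1 / d_in)), d_in, dh)
        p[[paste0(hp, "_wv")]] <- matrix(stats::rnorm(d_in * dh,
          sd = sqrt(1 / d_in)), d_in, dh)
        p[[paste0(hp, "_wek")]] <- matrix(stats::rnorm(edge_dim * dh,
          sd = sqrt(1 / edge_dim)), edge_dim, dh)
        p[[paste0(hp, "_wev")]] <- matrix(stats::rnorm(edge_dim * dh,
          sd = sqrt(1 / edge_dim)), edge_dim, dh)
      }
      p[[paste0(pref, "_wroot")]] <- matrix(stats::rnorm(d_in * h,
        sd = sqrt(1 / d_in)), d_in, h)
      p[[paste0(pref, "_b")]] <- matrix(0, 1L, h)
      p[[paste0(pref, "_topk")]] <- matrix(stats::rnorm(h, sd = 1), h, 1L)
    }
  } else {
    for (l in seq_len(config$n_layers)) {
      d_node <- if (l == 1L) node_dim else h
      d_edge <- if (l == 1L) edge_dim else h
      pref <- paste0("m", l)
      p <- c(p, nn_init_mlp(c(2L * d_node + d_edge + h, h, h),
                            paste0(pref, "_edge")))
      p <- c(p, nn_init_mlp(c(d_node + h + h, h, h),
                            paste0(pref, "_node")))
      p <- c(p, nn_init_mlp(c(h + h + h, h, h), paste0(pref, "_glob")))
    }
  }
  p <- c(p, nn_init_mlp(c(h, h, 1L), "pool_gate"))
  p <- c(p, nn_init_mlp(c(h, h), "pool_feat"))
  p <- c(p, nn_init_mlp(c(h, h, 1L), "head"))
  p
}

## ---- layer forwards ------------------------------------------------------

# One graph-transformer layer; edge features enter keys and values.
transformer_layer_fwd <- function(tape, ids, pref, X, src, dst, Evals,
                                  n, config) {
  h <- config$hidden
  dh <- h %/% config$heads
  root <- ad_matmul(tape, X, ids[[paste0(pref, "_wroot")]])
  if (length(src) == 0L) {
    return(ad_add_bias(tape, root, ids[[paste0(pref, "_b")]]))
  }
  E <- ad_leaf(tape, Evals)
  ones_dh <- ad_leaf(tape, matrix(1, dh, 1L))
  ones_row_dh <- ad_leaf(tape, matrix(1, 1L, dh))
  heads <- vector("list", config$heads)
  for (hd in seq_len(config$heads)) {
    hp <- paste0(pref, "_h", hd)
    q <- ad_matmul(tape, X, ids[[paste0(hp, "_wq")]])
    k <- ad_matmul(tape, X, ids[[paste0(hp, "_wk")]])
    v <- ad_matmul(tape, X, ids[[paste0(hp, "_wv")]])
    ke <- ad_add(tape, ad_gather(tape, k, src),
                 ad_matmul(tape, E, ids[[paste0(hp, "_wek")]]))
    ve <- ad_add(tape, ad_gather(tape, v, src),
                 ad_matmul(tape, E, ids[[paste0(hp, "_wev")]]))
    qe <- ad_gather(tape, q, dst)
    lg <- ad_scale(tape, ad_matmul(tape, ad_mul(tape, qe, ke), ones_dh),
                   1 / sqrt(dh))
    # numerically stable segment softmax over incoming edges per dst node
    lv <- ad_value(tape, lg)
    mx <- rep(0, n)
    mxagg <- tapply(lv[, 1], dst, max)
    mx[as.integer(names(mxagg))] <- mxagg
    sh <- ad_sub(tape, lg, ad_leaf(tape, matrix(mx[dst], ncol = 1L)))
    ex <- ad_exp(tape, sh)
    denom <- ad_scatter_sum(tape, ex, dst, n)
    alpha <- ad_div(tape, ex, ad_gather(tape, denom, dst))
    msg <- ad_mul(tape, ve, ad_matmul(tape, alpha, ones_row_dh))
    heads[[hd]] <- ad_scatter_sum(tape, msg, dst, n)
  }
  att <- heads[[1L]]
  if (config$heads > 1L) {
    for (hd in 2:config$heads) att <- ad_cbind(tape, att, heads[[hd]])
  }
  ad_add_bias(tape, ad_add(tape, att, root), ids[[paste0(pref, "_b")]])
}

# TopK pooling: learned projection score, keep ceil(ratio * n) nodes
# (ties: lower node index first), gate retained rows by tanh(score),
# restrict edges to retained nodes.
topk_fwd <- function(tape, ids, pref, X, src, dst, Evals, n, ratio) {
  p <- ids[[paste0(pref, "_topk")]]
  Xp <- ad_matmul(tape, X, p)
  pn <- ad_sqrt(tape, ad_sum(tape, ad_mul(tape, p, p)))
  pn_b <- ad_matmul(tape, ad_leaf(tape, matrix(1, n, 1L)), pn)
  s <- ad_div(tape, Xp, pn_b)
  sv <- ad_value(tape, s)[, 1]
  k <- max(1L, ceiling(ratio * n))
  keep <- sort(order(-sv, seq_along(sv))[seq_len(k)])
  gate <- ad_tanh(tape, ad_gather(tape, s, keep))
  d <- ncol(ad_value(tape, X))
  Xk <- ad_mul(tape, ad_gather(tape, X, keep),
               ad_matmul(tape, gate, ad_leaf(tape, matrix(1, 1L, d))))
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  sel <- which(src %in% keep & dst %in% keep)
  list(X = Xk, src = remap[src[sel]], dst = remap[dst[sel]],
       Evals = Evals[sel, , drop = FALSE], n = k)
}

# MetaLayer block: edge, node then global update, each a small MLP + ReLU.
metalayer_fwd <- function(tape, ids, pref, X, Eid, U, src, dst, n,
                          config) {
  h <- config$hidden
  m <- length(src)
  Ub_n <- ad_matmul(tape, ad_leaf(tape, matrix(1, n, 1L)), U)
  if (m > 0L) {
    Ub_m <- ad_matmul(tape, ad_leaf(tape, matrix(1, m, 1L)), U)
    he <- ad_cbind(tape, ad_cbind(tape, ad_gather(tape, X, src),
                                  ad_gather(tape, X, dst)),
                   ad_cbind(tape, Eid, Ub_m))
    E2 <- ad_relu(tape, nn_mlp(tape, he, ids, paste0(pref, "_edge"), 2L,
                               config$use_norm))
    cnt <- tabulate(dst, nbins = n)
    agg <- ad_scatter_sum(tape, E2, dst, n)
    agg <- ad_mul(tape, agg,
                  ad_leaf(tape, matrix(1 / pmax(cnt, 1L), n, h)))
    emean <- ad_matmul(tape, ad_leaf(tape, matrix(1 / m, 1L, m)), E2)
  } else {
    E2 <- ad_leaf(tape, matrix(0, 0L, h))
    agg <- ad_leaf(tape, matrix(0, n, h))
    emean <- ad_leaf(tape, matrix(0, 1L, h))
  }
  hv <- ad_cbind(tape, ad_cbind(tape, X, agg), Ub_n)
  X2 <- ad_relu(tape, nn_mlp(tape, hv, ids, paste0(pref, "_node"), 2L,
                             config$use_norm))
  nmean <- ad_matmul(tape, ad_leaf(tape, matrix(1 / n, 1L, n)), X2)
  hu <- ad_cbind(tape, ad_cbind(tape, nmean, emean), U)
  U2 <- ad_relu(tape, nn_mlp(tape, hu, ids, paste0(pref, "_glob"), 2L))
  list(X = X2, E = E2, U = U2)
}

# Global attention pooling: softmax over a learned per-node gate, weighted
# sum of transformed node features. Permutation invariant.
global_attention_fwd <- function(tape, ids, X, n) {
  gate <- nn_mlp(tape, X, ids, "pool_gate", 2L)
  gv <- ad_value(tape, gate)
  sh <- ad_sub(tape, gate, ad_leaf(tape, matrix(max(gv), n, 1L)))
  ex <- ad_exp(tape, sh)
  denom <- ad_matmul(tape, ad_leaf(tape, matrix(1, 1L, n)), ex)
  alpha <- ad_div(tape, ex,
                  ad_matmul(tape, ad_leaf(tape, matrix(1, n, 1L)), denom))
  feat <- nn_mlp(tape, X, ids, "pool_feat", 1L)
  ad_matmul(tape, ad_transpose(tape, alpha), feat)
}

# Full forward pass; returns tape node ids of the score (1x1, in (0,1))
# and the global embedding (1 x hidden).
backbone_fwd <- function(tape, ids, config, gd, dropout = 0) {
  X <- ad_leaf(tape, gd$node_x)
  src <- gd$src; dst <- gd$dst; Evals <- gd$edge_x; n <- gd$n
  if (config$variant == "transformer") {
    for (l in seq_len(config$n_layers)) {
      pref <- paste0("t", l)
      X <- ad_relu(tape, transformer_layer_fwd(tape, ids, pref, X, src,
                                               dst, Evals, n, config))
      if (config$use_norm) X <- nn_layernorm(tape, X)
      X <- nn_dropout(tape, X, dropout)
      pooled <- topk_fwd(tape, ids, pref, X, src, dst, Evals, n,
                         config$topk_ratio)
      X <- pooled$X; src <- pooled$src; dst <- pooled$dst
      Evals <- pooled$Evals; n <- pooled$n
    }
  } else {
    Eid <- ad_leaf(tape, Evals)
    U <- ad_leaf(tape, matrix(0, 1L, config$hidden))
    for (l in seq_len(config$n_layers)) {
      out <- metalayer_fwd(tape, ids, paste0("m", l), X, Eid, U, src,
                           dst, n, config)
      X <- out$X; Eid <- out$E; U <- out$U
      X <- nn_dropout(tape, X, dropout)
    }
  }
  emb <- global_attention_fwd(tape, ids, X, n)
  score <- ad_sigmoid(tape, nn_mlp(tape, emb, ids, "head", 2L))
  list(score = score, embedding = emb)
}

## ---- user-facing prediction & training -----------------------------------

#' Initialise a backbone model
#'
#' @param config a [backbone_config()]
#' @param node_dim node feature width (83 for the core layout)
#' @param edge_dim edge feature width (10)
#' @param seed RNG seed for weight initialisation
#' @return an (untrained) `meqa_backbone`
#' @export
new_backbone <- function(config, node_dim, edge_dim = 10L, seed = 1L) {
  structure(list(config = config,
                 params = backbone_init(config, node_dim, edge_dim, seed),
                 node_dim = node_dim, edge_dim = edge_dim,
                 log = NULL),
            class = "meqa_backbone")
}

#' Predict a quality score (and global embedding) for one graph
#'
#' Evaluation mode: no dropout, fully deterministic.
#'
#' @param object a `meqa_backbone`
#' @param gd graph input from [graph_input()]
#' @param ... unused
#' @return list with `score` (strictly in (0,1)) and `embedding`
#'   (1 x hidden matrix)
#' @export
predict.meqa_backbone <- function(object, gd, ...) {
  tape <- ad_tape()
  ids <- ad_params(tape, object$params)
  out <- backbone_fwd(tape, ids, object$config, gd, dropout = 0)
  list(score = ad_value(tape, out$score)[1L, 1L],
       embedding = ad_value(tape, out$embedding))
}

#' Train a backbone with weighted L1, Adam and AutoClip
#'
#' Weights are the inverse frequency of the true scores over ten equal
#' bins (computed on the training split), the standard correction for a
#' skewed score distribution. Gradients are clipped to the AutoClip
#' percentile of the gradient-norm history.
#'
#' @param backbone a `meqa_backbone`
#' @param graphs list of graph inputs ([graph_input()])
#' @param labels true scores in (0,1), one per graph
#' @param epochs training epochs
#' @param lr Adam learning rate
#' @param val_idx indices of `graphs` held out for validation (default:
#'   every fifth graph)
#' @param clip_percentile AutoClip percentile (default 10)
#' @param seed RNG seed controlling data order and dropout
#' @param verbose print per-epoch losses
#' @return the trained `meqa_backbone`; `$log` holds a data.frame with
#'   columns epoch, train_loss, val_loss
#' @export
train_backbone <- function(backbone, graphs, labels, epochs = 30L,
                           lr = 1e-3, val_idx = NULL,
                           clip_percentile = 10, seed = 1L,
                           verbose = FALSE) {
  stopifnot(length(graphs) == length(labels), all(labels > 0),
            all(labels < 1))
  set.seed(seed)
  if (is.null(val_idx)) {
    val_idx <- if (length(graphs) >= 5L) {
      seq(5L, length(graphs), by = 5L)
    } else {
      length(graphs)
    }
  }
  tr_idx <- setdiff(seq_along(graphs), val_idx)
  w <- numeric(length(labels))
  w[tr_idx] <- nn_inverse_frequency_weights(labels[tr_idx])
  params <- backbone$params
  state <- nn_adam_state(params)
  history <- numeric(0)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; tw <- 0
    for (i in ord) {
      tape <- ad_tape()
      ids <- ad_params(tape, params)
      out <- backbone_fwd(tape, ids, backbone$config, graphs[[i]],
                          dropout = backbone$config$dropout)
      yhat <- out$score
      res <- ad_abs(tape, ad_sub(tape, yhat,
                                 ad_leaf(tape, matrix(labels[i], 1L))))
      loss <- ad_scale(tape, res, w[i])
      grads <- ad_backward(tape, loss)
      g <- ad_param_grads(tape, grads, ids, params)
      nrm <- nn_grad_norm(g)
      ac <- autoclip_step(history, nrm, clip_percentile)
      history <- ac$history
      g <- nn_clip_grads(g, nrm, ac$threshold)
      st <- nn_adam_step(params, g, state, lr = lr)
      params <- st$params; state <- st$state
      tl <- tl + w[i] * abs(ad_value(tape, yhat)[1L] - labels[i])
      tw <- tw + w[i]
    }
    bb <- backbone; bb$params <- params
    vl <- mean(vapply(val_idx, function(i) {
      abs(predict.meqa_backbone(bb, graphs[[i]])$score - labels[i])
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / tw,
                                 val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep, tl / tw, vl))
    }
  }
  backbone$params <- params
  backbone$log <- log
  backbone
}
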