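# Minimal tape-based reverse-mode automatic differentiation on dense
# matrices. All graph-network and energy-net training in this package runs
# through these primitives; each op records a vector-Jacobian product
# closure on the tape. Values are always numeric matrices.

#' Create an empty autodiff tape
#'
#' A tape records the forward computation as a sequence of nodes; calling
#' [ad_backward()] replays it in reverse to accumulate gradients. Tapes are
#' cheap, single-use objects: build one per forward pass.
#'
#' @return An environment holding the tape state.
#' @keywords internal
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$nodes <- vector("list", 256L)
  t
}

ad_push <- function(tape, value, parents = integer(0), vjp = NULL) {
  stopifnot(is.matrix(value))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- list(value = value, parents = parents, vjp = vjp)
  tape$n
}

#' @keywords internal
ad_value <- function(tape, id) {
  force(id)  # inline sub-expressions must push their nodes first
  tape$nodes[[id]]$value
}

# Leaf nodes: constants take no gradient, parameters do (distinguished only
# by whether the caller collects their gradient after backward).
ad_leaf <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_push(tape, x)
}

#' Reverse pass: gradients of node `id` w.r.t. every tape node
#'
#' @param tape tape from [ad_tape()] after a forward pass
#' @param id node id of the (typically 1x1) output
#' @return list of gradients indexed by node id (NULL where not reached)
#' @keywords internal
ad_backward <- function(tape, id) {
  grads <- vector("list", tape$n)
  v <- ad_value(tape, id)
  grads[[id]] <- matrix(1, nrow(v), ncol(v))
  for (k in seq(tape$n, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    nd <- tape$nodes[[k]]
    if (is.null(nd$vjp)) next
    pg <- nd$vjp(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

## ---- primitive operations ------------------------------------------------

ad_matmul <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_push(tape, A %*% B, c(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

ad_add <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_push(tape, A + B, c(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_push(tape, A - B, c(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_div <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_push(tape, A / B, c(a, b),
          function(g) list(g / B, -g * A / (B * B)))
}

# Add a 1 x d bias row to every row of an n x d matrix.
ad_add_bias <- function(tape, a, bias) {
  A <- ad_value(tape, a); B <- ad_value(tape, bias)
  v <- sweep(A, 2L, as.vector(B), "+")
  ad_push(tape, v, c(a, bias),
          function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

ad_scale <- function(tape, a, s) {
  A <- ad_value(tape, a)
  ad_push(tape, A * s, a, function(g) list(g * s))
}

ad_relu <- function(tape, a) {
  A <- ad_value(tape, a)
  mask <- A > 0
  ad_push(tape, A * mask, a, function(g) list(g * mask))
}

ad_tanh <- function(tape, a) {
  V <- tanh(ad_value(tape, a))
  ad_push(tape, V, a, function(g) list(g * (1 - V * V)))
}

ad_sigmoid <- function(tape, a) {
  V <- stats::plogis(ad_value(tape, a))
  ad_push(tape, V, a, function(g) list(g * V * (1 - V)))
}

ad_exp <- function(tape, a) {
  V <- exp(ad_value(tape, a))
  ad_push(tape, V, a, function(g) list(g * V))
}

ad_log <- function(tape, a) {
  A <- ad_value(tape, a)
  ad_push(tape, log(A), a, function(g) list(g / A))
}

ad_sqrt <- function(tape, a) {
  V <- sqrt(ad_value(tape, a))
  ad_push(tape, V, a, function(g) list(g / (2 * V)))
}

# |x| with subgradient 0 at 0 (standard choice for L1 losses).
ad_abs <- function(tape, a) {
  A <- ad_value(tape, a)
  s <- sign(A)
  ad_push(tape, abs(A), a, function(g) list(g * s))
}

ad_sum <- function(tape, a) {
  A <- ad_value(tape, a)
  ad_push(tape, matrix(sum(A), 1L, 1L), a,
          function(g) list(matrix(g[1L], nrow(A), ncol(A))))
}

ad_mean <- function(tape, a) {
  A <- ad_value(tape, a)
  n <- length(A)
  ad_push(tape, matrix(mean(A), 1L, 1L), a,
          function(g) list(matrix(g[1L] / n, nrow(A), ncol(A))))
}

# Row selection (with repetition allowed): out[k, ] = a[idx[k], ].
ad_gather <- function(tape, a, idx) {
  A <- ad_value(tape, a)
  idx <- as.integer(idx)
  ad_push(tape, A[idx, , drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# Segment sum: out has n rows; out[s, ] = sum of a's rows with idx == s.
ad_scatter_sum <- function(tape, a, idx, n) {
  A <- ad_value(tape, a)
  idx <- as.integer(idx)
  out <- matrix(0, n, ncol(A))
  rs <- rowsum(A, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  ad_push(tape, out, a, function(g) list(g[idx, , drop = FALSE]))
}

ad_cbind <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ka <- ncol(A)
  ad_push(tape, cbind(A, B), c(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

# Column-major reshape; gradient reshapes back.
ad_reshape <- function(tape, a, nr, nc) {
  A <- ad_value(tape, a)
  stopifnot(length(A) == nr * nc)
  ad_push(tape, matrix(as.vector(A), nr, nc), a,
          function(g) list(matrix(as.vector(g), nrow(A), ncol(A))))
}

ad_transpose <- function(tape, a) {
  A <- ad_value(tape, a)
  ad_push(tape, t(A), a, function(g) list(t(g)))
}

## ---- parameter plumbing --------------------------------------------------

# Push a named list of parameter matrices onto a tape; returns ids.
ad_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

# Collect gradients for the ids returned by ad_params (zeros where unused).
ad_param_grads <- function(tape, grads, ids, params) {
  out <- params
  for (nm in names(ids)) {
    g <- grads[[ids[[nm]]]]
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}
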