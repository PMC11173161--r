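featured_dimer_input <- function(seed = 3L, chain_length = 10L) {
  s <- toy_dimer(seed = seed, chain_length = chain_length)
  g <- build_graph(s)
  graph_input(g, assemble_node_features(s),
              assemble_edge_features(g, s))
}

test_that("predictions are bounded, deterministic and permutation invariant", {
  gd <- featured_dimer_input()
  for (variant in c("transformer", "metalayer")) {
    bb <- new_backbone(backbone_config(variant = variant), 83L, seed = 5L)
    p1 <- predict(bb, gd)
    expect_gt(p1$score, 0); expect_lt(p1$score, 1)
    expect_equal(dim(p1$embedding), c(1L, 16L))
    expect_identical(predict(bb, gd)$score, p1$score)
    set.seed(42L)
    perm <- sample(gd$n)
    p2 <- predict(bb, permute_graph_input(gd, perm))
    expect_equal(p2$score, p1$score, tolerance = 1e-9)
    expect_equal(p2$embedding, p1$embedding, tolerance = 1e-9)
  }
})

test_that("an isolated node sees only its own features", {
  cfg <- backbone_config(variant = "transformer", topk_ratio = 1)
  bb <- new_backbone(cfg, 5L, seed = 7L)
  set.seed(8)
  x <- matrix(rnorm(10), 2L, 5L)
  run_layer <- function(node_x) {
    tape <- ad_tape()
    ids <- meqa:::ad_params(tape, bb$params)
    out <- meqa:::transformer_layer_fwd(tape, ids, "t1",
                                        ad_leaf(tape, node_x),
                                        integer(0), integer(0),
                                        matrix(0, 0L, 10L), 2L, cfg)
    ad_value(tape, out)
  }
  o1 <- run_layer(x)
  x2 <- x; x2[2L, ] <- rnorm(5)
  o2 <- run_layer(x2)
  expect_equal(o1[1L, ], o2[1L, ])   # node 1 unaffected by node 2
  expect_false(isTRUE(all.equal(o1[2L, ], o2[2L, ])))
})

test_that("TopK pooling keeps ceil(ratio n) nodes with stable ties", {
  cfg <- backbone_config(variant = "transformer", hidden = 4L, heads = 1L)
  bb <- new_backbone(cfg, 4L, seed = 9L)
  run_topk <- function(X, ratio, pvec) {
    params <- bb$params
    params$t1_topk <- matrix(pvec, ncol = 1L)
    tape <- ad_tape()
    ids <- meqa:::ad_params(tape, params)
    meqa:::topk_fwd(tape, ids, "t1", ad_leaf(tape, X), integer(0),
                    integer(0), matrix(0, 0L, 10L), nrow(X), ratio)
  }
  X <- matrix(rnorm(40), 10L, 4L)
  expect_equal(run_topk(X, 1.0, c(1, 0, 0, 0))$n, 10L)
  expect_equal(run_topk(X, 0.5, c(1, 0, 0, 0))$n, 5L)
  # all-equal scores: the lowest node indices are retained first
  Xc <- cbind(rep(2, 10L), matrix(seq_len(30L), 10L, 3L))
  params <- bb$params
  params$t1_topk <- matrix(c(1, 0, 0, 0), ncol = 1L)
  tape <- ad_tape()
  ids <- meqa:::ad_params(tape, params)
  tk <- meqa:::topk_fwd(tape, ids, "t1", ad_leaf(tape, Xc), integer(0),
                        integer(0), matrix(0, 0L, 10L), 10L, 0.3)
  expect_equal(tk$n, 3L)
  kept <- ad_value(tape, tk$X)
  expect_equal(kept[, 2L], Xc[1:3, 2L] * tanh(2))
})

test_that("global attention pooling reduces to the mean under a flat gate", {
  cfg <- backbone_config(variant = "metalayer", hidden = 6L)
  bb <- new_backbone(cfg, 6L, seed = 11L)
  params <- bb$params
  # zero the gate network: softmax of a constant is uniform
  for (nm in grep("^pool_gate", names(params), value = TRUE)) {
    params[[nm]] <- params[[nm]] * 0
  }
  set.seed(12)
  X <- matrix(rnorm(30), 5L, 6L)
  tape <- ad_tape()
  ids <- meqa:::ad_params(tape, params)
  emb <- meqa:::global_attention_fwd(tape, ids, ad_leaf(tape, X), 5L)
  feat <- X %*% params$pool_feat_l1_w +
    matrix(params$pool_feat_l1_b, 5L, 6L, byrow = TRUE)
  expect_equal(drop(ad_value(tape, emb)), colMeans(feat),
               tolerance = 1e-10)
  # single node: pooled embedding is that node's transformed features
  tape2 <- ad_tape()
  ids2 <- meqa:::ad_params(tape2, bb$params)
  emb1 <- meqa:::global_attention_fwd(tape2, ids2,
                                      ad_leaf(tape2, X[1L, , drop = FALSE]),
                                      1L)
  feat1 <- X[1L, , drop = FALSE] %*% bb$params$pool_feat_l1_w +
    bb$params$pool_feat_l1_b
  expect_equal(ad_value(tape2, emb1), feat1, tolerance = 1e-10)
})

test_that("a zero-weight MetaLayer outputs its broadcast biases", {
  cfg <- backbone_config(variant = "metalayer", hidden = 4L)
  bb <- new_backbone(cfg, 4L, seed = 13L)
  params <- lapply(bb$params, function(p) p * 0)
  params$m1_edge_l2_b <- matrix(c(1, -2, 3, -4), 1L, 4L)
  tape <- ad_tape()
  ids <- meqa:::ad_params(tape, params)
  X <- matrix(rnorm(12), 3L, 4L)
  out <- meqa:::metalayer_fwd(tape, ids, "m1", ad_leaf(tape, X),
                              ad_leaf(tape, matrix(0, 2L, 10L)),
                              ad_leaf(tape, matrix(0, 1L, 4L)),
                              src = c(1L, 2L), dst = c(2L, 3L), n = 3L,
                              config = cfg)
  ev <- ad_value(tape, out$E)
  expect_equal(ev, matrix(rep(pmax(c(1, -2, 3, -4), 0), each = 2L),
                          2L, 4L))
})

test_that("weighted L1 loss follows its definition", {
  expect_equal(weighted_l1_loss(c(0.2, 0.8), c(0.1, 0.6)),
               mean(c(0.1, 0.2)))
  expect_equal(weighted_l1_loss(c(0.3, 0.3), c(0.3, 0.3)), 0)
  expect_equal(weighted_l1_loss(c(0.1, 0.9), c(0.0, 0.0),
                                weights = c(2, 0)), 0.1)
  expect_error(weighted_l1_loss(1, 2, weights = 0), "positive")
  expect_error(weighted_l1_loss(1, 2, weights = -1), "non-negative")
})

test_that("AutoClip thresholds follow the percentile of the history", {
  r <- autoclip_step(rep(3.5, 20L), 3.5, percentile = 10)
  expect_equal(r$threshold, 3.5)
  r2 <- autoclip_step(as.numeric(1:99), 100, percentile = 10)
  expect_equal(r2$threshold, unname(quantile(1:100, 0.1)))
  expect_equal(r2$threshold, 10.9)
  # clipping contract: applied norm never exceeds the threshold
  g <- list(a = matrix(3, 2L, 2L))
  nrm <- meqa:::nn_grad_norm(g)
  gc <- meqa:::nn_clip_grads(g, nrm, r$threshold)
  expect_lte(meqa:::nn_grad_norm(gc), r$threshold + 1e-12)
  # first step: threshold equals the incoming norm, so no clipping
  r3 <- autoclip_step(numeric(0), 7)
  expect_equal(r3$threshold, 7)
})

test_that("training reduces validation L1 on a learnable graph label", {
  ds <- make_graph_label_dataset(30L, chain_length = 8L, seed = 17L)
  bb <- new_backbone(backbone_config(variant = "transformer"), 83L,
                     seed = 19L)
  bb <- train_backbone(bb, ds$graphs, ds$labels, epochs = 5L, lr = 3e-3,
                       seed = 23L)
  expect_equal(nrow(bb$log), 5L)
  expect_lt(bb$log$val_loss[5L], bb$log$val_loss[1L])
})

test_that("metalayer variant also trains", {
  ds <- make_graph_label_dataset(20L, chain_length = 8L, seed = 29L)
  bb <- new_backbone(backbone_config(variant = "metalayer"), 83L,
                     seed = 31L)
  bb <- train_backbone(bb, ds$graphs, ds$labels, epochs = 4L, lr = 3e-3,
                       seed = 37L)
  expect_lt(bb$log$val_loss[4L], bb$log$val_loss[1L])
})
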