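test_that("logit and sigmoid are exact inverses inside the clamp range", {
  expect_equal(logit_score(0.5), 0)
  expect_equal(sigmoid_score(logit_score(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(logit_score(1.0, eps = 1e-6), log((1 - 1e-6) / 1e-6),
               tolerance = 1e-9)
  expect_equal(logit_score(1.0, eps = 1e-6), 13.8155, tolerance = 1e-4)
  p <- seq(1e-6, 1 - 1e-6, length.out = 101L)
  expect_equal(sigmoid_score(logit_score(p)), p, tolerance = 1e-9)
})

test_that("the quartile constant comes from the normal inverse CDF", {
  expect_equal(quartile_z(), qnorm(0.75))
  expect_equal(quartile_z(), 0.675, tolerance = 1e-3)
})

test_that("sliding sigma follows its two-branch definition", {
  z <- 0.675
  expect_equal(sliding_sigma(0.5, 0.2, z = z),
               (logit_score(0.7) - logit_score(0.5)) / z)
  expect_equal(sliding_sigma(0.5, 0.2, z = z), 1.2553, tolerance = 1e-4)
  # upper branch unavailable when mu + gamma >= 1
  expect_equal(sliding_sigma(0.9, 0.2, z = z),
               (logit_score(0.9) - logit_score(0.7)) / z)
  mus <- seq(0.01, 0.99, by = 0.01)
  for (g in c(0.05, 0.1, 0.3)) {
    expect_true(all(sliding_sigma(mus, g) > 0))
  }
})

test_that("contrastive targets have the advertised distribution", {
  cfg <- ebm_config(M = 100001L, beta = 0.05, gamma = 0.1)
  set.seed(41)
  st <- sample_targets(0.7, cfg)
  draws <- vapply(st$adversarial, `[[`, numeric(1), "value")
  mu <- logit_score(0.7)
  sigma <- sliding_sigma(0.7, 0.1)
  se <- sigma / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
  expect_lt(abs(sd(draws) - sigma) / sigma, 0.02)
  # proposal log densities are the normal density at the draw
  expect_equal(st$adversarial[[1L]]$log_density,
               dnorm(st$adversarial[[1L]]$value, mu, sigma, log = TRUE))
  # vanishing beta pins the noisy true target at the true logit
  cfg2 <- ebm_config(M = 2L, beta = 1e-12, gamma = 0.1)
  set.seed(42)
  st2 <- sample_targets(0.42, cfg2)
  expect_equal(st2$y0$value, logit_score(0.42), tolerance = 1e-4)
})

test_that("contrastive loss matches constants, limits and the naive oracle", {
  # all scores zero, all densities equal, 7 adversarial: J = ln(8)
  sc <- matrix(0, 5L, 8L)
  ld <- matrix(0.3, 5L, 8L)
  expect_equal(nce_loss(sc, ld), log(8), tolerance = 1e-12)
  # saturation: a dominant true score drives the loss to zero
  sc2 <- sc; sc2[, 1L] <- 200
  expect_lt(nce_loss(sc2, ld), 1e-12)
  # non-negativity on random inputs, and agreement with the naive form
  set.seed(43)
  for (k in 1:20) {
    s <- matrix(rnorm(24, sd = 2), 4L, 6L)
    d <- matrix(rnorm(24), 4L, 6L)
    expect_gte(nce_loss(s, d), 0)
    expect_equal(nce_loss(s, d), naive_nce_loss(s, d), tolerance = 1e-6)
  }
  expect_error(nce_loss(matrix(c(Inf, 0), 1L), matrix(0, 1L, 2L)),
               "non-finite")
})

test_that("the energy net is deterministic and respects degenerate weights", {
  cfg <- ebm_config(hidden = c(8L, 8L), skip_depth = 2L)
  net <- new_ebm(cfg, embed_dim = 4L, seed = 47L)
  X <- matrix(rnorm(8), 2L, 4L)
  y <- c(-1, 2)
  expect_identical(ebm_energy(net, X, y), ebm_energy(net, X, y))
  expect_true(all(is.finite(ebm_energy(net, X[1L, ],
                                       logit_score(seq(0.001, 0.999,
                                                       by = 0.01))))))
  # zero weights: output is the final bias, independent of y
  net0 <- net
  net0$params <- lapply(net0$params, function(p) p * 0)
  net0$params$e_l3_b <- matrix(1.5, 1L, 1L)
  expect_equal(ebm_energy(net0, X, y), c(1.5, 1.5))
})

test_that("grid inference matches an exhaustive scan and known shapes", {
  # hand-built net with energy |y - logit(0.3)|
  cfg <- ebm_config(hidden = 2L, skip_depth = 0L, grid_n = 1000L)
  net <- new_ebm(cfg, embed_dim = 3L, seed = 53L)
  cstar <- logit_score(0.3)
  net$params$e_l1_w <- rbind(matrix(0, 3L, 2L), c(1, -1))
  net$params$e_l1_b <- matrix(c(-cstar, cstar), 1L)
  net$params$e_l2_w <- matrix(c(1, 1), 2L, 1L)
  net$params$e_l2_b <- matrix(0, 1L, 1L)
  X <- matrix(0, 1L, 3L)
  expect_equal(ebm_energy(net, X, cstar + 2), 2, tolerance = 1e-12)
  expect_lt(abs(grid_inference(net, X) - 0.3), 1 / 1000)
  # monotone decreasing energy picks the largest grid score
  net2 <- net
  net2$params$e_l1_w <- rbind(matrix(0, 3L, 2L), c(1, 0))
  net2$params$e_l1_b <- matrix(c(20, 0), 1L)
  net2$params$e_l2_w <- matrix(c(-1, 0), 2L, 1L)  # energy = -(y + 20)
  expect_equal(grid_inference(net2, X), (1000 - 0.5) / 1000)
  # exhaustive oracle on a randomly initialised net
  net3 <- new_ebm(ebm_config(grid_n = 257L), embed_dim = 5L, seed = 59L)
  X3 <- matrix(rnorm(5), 1L)
  s <- (seq_len(257L) - 0.5) / 257L
  e <- vapply(s, function(si) {
    ebm_energy(net3, X3, logit_score(si, net3$cfg$eps_clamp))
  }, numeric(1))
  expect_equal(grid_inference(net3, X3), s[which.min(e)])
})

test_that("a short contrastive training run reduces the objective", {
  ds <- make_embedding_dataset(300L, width = 8L, seed = 61L)
  cfg <- ebm_config(M = 17L, hidden = c(16L, 16L))
  net <- new_ebm(cfg, embed_dim = 8L, seed = 67L)
  net <- train_ebm(net, ds$X, ds$score, epochs = 4L, batch = 32L,
                   lr = 2e-3, seed = 71L)
  expect_equal(nrow(net$log), 4L)
  expect_lt(net$log$train_loss[4L], net$log$train_loss[1L])
  expect_lt(net$log$val_mae[4L], net$log$val_mae[1L])
})
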