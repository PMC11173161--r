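test_that("toy complex generation is deterministic and in contact", {
  sp <- decoy_spec(n_chains = 2L, chain_length = 20L, seed = 5L)
  s <- generate_toy_complex(sp)
  expect_equal(n_residues_of(s), 40L)
  expect_equal(length(s$chain_ids), 2L)
  g <- build_graph(s)
  expect_gte(sum(g$cross_chain_mask), 1L)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_complex(generate_toy_complex(sp), f1)
  write_pdb_complex(generate_toy_complex(sp), f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_toy_complex(decoy_spec(n_chains = 3L, chain_length = 8L,
                                        seed = 6L))
  expect_equal(s3$chain_ids, c("A", "B", "C"))
  rt <- parse_structure(f1)
  expect_equal(length(rt$chain_ids), 2L)
})

test_that("null perturbation reproduces the native coordinates", {
  s <- toy_dimer(seed = 7L)
  sp0 <- decoy_spec(rigid_rotation_max = 0, rigid_translation_max = 0,
                    jitter_sd = 0)
  set.seed(1)
  d <- perturb_decoy(s, sp0)
  cc <- paste0(rep(c("n", "ca", "c"), each = 3), "_", c("x", "y", "z"))
  expect_equal(as.matrix(d$residues[, cc]), as.matrix(s$residues[, cc]),
               tolerance = 1e-12)
  expect_equal(fold_label(s, d), 1, tolerance = 1e-9)
  expect_equal(interface_label(s, d), 1)
})

test_that("pure jitter displaces atoms by about sd * sqrt(3) RMS", {
  s <- generate_toy_complex(decoy_spec(n_chains = 2L, chain_length = 60L,
                                       seed = 8L))
  spj <- decoy_spec(rigid_rotation_max = 0, rigid_translation_max = 0,
                    jitter_sd = 0.1)
  set.seed(9)
  disp <- numeric(0)
  for (k in 1:10) {
    d <- perturb_decoy(s, spj)
    cc <- paste0(rep(c("n", "ca", "c"), each = 3), "_", c("x", "y", "z"))
    dm <- as.matrix(d$residues[, cc]) - as.matrix(s$residues[, cc])
    disp <- c(disp, sqrt(rowSums(dm[, 1:3]^2)), sqrt(rowSums(dm[, 4:6]^2)),
              sqrt(rowSums(dm[, 7:9]^2)))
  }
  expect_equal(sqrt(mean(disp^2)), 0.1 * sqrt(3), tolerance = 0.03)
})

test_that("fold label is invariant to rigid motion and TM-like in scale", {
  s <- toy_dimer(seed = 10L, chain_length = 15L)
  expect_equal(fold_label(s, rigidly_move(s, 11L)), 1, tolerance = 1e-9)
  expect_equal(meqa:::tm_d0(120L), 1.24 * 105^(1 / 3) - 1.8)
  expect_equal(meqa:::tm_d0(120L), 4.050, tolerance = 1e-3)
  expect_equal(meqa:::tm_d0(10L), 0.5)
  expect_equal(meqa:::tm_d0(16L), 0.5)  # floor engages for short chains
  expect_error(fold_label(s, toy_dimer(seed = 10L, chain_length = 14L)),
               "length")
})

test_that("our Kabsch superposition matches the bio3d reference", {
  set.seed(12)
  P <- matrix(rnorm(60), 20L, 3L)
  R <- meqa:::random_rotation(170)
  Q <- sweep(P %*% t(R), 2L, c(3, -2, 8), "+") +
    matrix(rnorm(60, sd = 0.3), 20L, 3L)
  P0 <- sweep(P, 2L, colMeans(P)); Q0 <- sweep(Q, 2L, colMeans(Q))
  ours <- sqrt(mean(rowSums((P0 %*% meqa:::kabsch_rotation(P0, Q0) -
                               Q0)^2)))
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("interface label equals a manual contact enumeration", {
  s <- toy_dimer(seed = 13L, chain_length = 10L)
  set.seed(14)
  d <- perturb_decoy(s, decoy_spec(rigid_translation_max = 3,
                                   jitter_sd = 0.3))
  manual <- function(x) {
    xyz <- meqa:::representative_coords(x)
    ch <- x$residues$chain
    D <- as.matrix(dist(xyz))
    keys <- character(0)
    for (i in 1:(nrow(D) - 1)) for (j in (i + 1):nrow(D)) {
      if (ch[i] != ch[j] && D[i, j] <= 8) {
        keys <- c(keys, paste(i, j, sep = ":"))
      }
    }
    keys
  }
  cn <- manual(s); cd <- manual(d)
  expect_equal(interface_label(s, d),
               length(intersect(cn, cd)) / length(union(cn, cd)))
  far <- meqa:::transform_structure(s, diag(3), c(100, 0, 0))
  far$residues[far$residues$chain == "B",
               c("n_x", "ca_x", "c_x", "cb_x")] <-
    far$residues[far$residues$chain == "B",
                 c("n_x", "ca_x", "c_x", "cb_x")] + 100
  expect_equal(interface_label(s, far), 0)
})

test_that("labels degrade on average with perturbation magnitude", {
  s <- toy_dimer(seed = 15L, chain_length = 12L)
  spec_small <- decoy_spec(rigid_rotation_max = 2,
                           rigid_translation_max = 0.5, jitter_sd = 0.05)
  spec_large <- decoy_spec(rigid_rotation_max = 25,
                           rigid_translation_max = 6, jitter_sd = 0.5)
  set.seed(16)
  small_f <- small_i <- large_f <- large_i <- numeric(50L)
  for (k in 1:50) {
    ds <- perturb_decoy(s, spec_small)
    dl <- perturb_decoy(s, spec_large)
    small_f[k] <- fold_label(s, ds); small_i[k] <- interface_label(s, ds)
    large_f[k] <- fold_label(s, dl); large_i[k] <- interface_label(s, dl)
  }
  expect_gt(mean(small_f), mean(large_f))
  expect_gt(mean(small_i), mean(large_i))
})

test_that("labelled decoy sets are graded and write out cleanly", {
  sp <- decoy_spec(seed = 17L, chain_length = 8L)
  ds <- make_labeled_decoy_set(sp, n_decoys = 6L)
  expect_equal(nrow(ds$labels), 6L)
  expect_true(all(ds$labels$fold_label > 0 & ds$labels$fold_label <= 1))
  expect_true(all(ds$labels$interface_label >= 0 &
                    ds$labels$interface_label <= 1))
  dir <- withr::local_tempdir()
  write_decoy_set(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_equal(length(list.files(dir, pattern = "\\.pdb$")), 7L)
})

test_that("embedding datasets are exactly logistic-linear when noiseless", {
  ds <- make_embedding_dataset(500L, width = 6L, noise_sd = 0, seed = 18L)
  expect_equal(ds$score,
               pmin(pmax(plogis(drop(ds$X %*% ds$w) + ds$b), 1e-4),
                    1 - 1e-4))
  ds2 <- make_embedding_dataset(500L, width = 6L, noise_sd = 0,
                                seed = 18L)
  expect_identical(ds$X, ds2$X)
  # OLS on the logit recovers the hidden weights
  big <- make_embedding_dataset(10000L, width = 6L, noise_sd = 0,
                                seed = 19L)
  keep <- big$score > 1e-4 & big$score < 1 - 1e-4
  fit <- lm.fit(cbind(1, big$X[keep, ]), qlogis(big$score[keep]))
  expect_lt(max(abs(fit$coefficients[-1L] - big$w) / abs(big$w)), 0.05)
})

test_that("generated structures survive the full pipeline", {
  for (seed in c(20L, 21L)) {
    sp <- decoy_spec(n_chains = sample(2:3, 1L), chain_length = 8L,
                     seed = seed)
    s <- generate_toy_complex(sp)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb_complex(s, f)
    fm <- featurize_model(f)
    bb <- new_backbone(backbone_config(variant = "metalayer"), 83L,
                       seed = seed)
    p <- predict(bb, fm$input)
    expect_gt(p$score, 0); expect_lt(p$score, 1)
  }
})
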