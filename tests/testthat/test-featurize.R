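test_that("one-hot encoding follows the fixed residue ordering", {
  expect_equal(which(one_hot_aa("ALA") == 1), 1L)
  expect_equal(which(one_hot_aa("VAL") == 1), 20L)
  for (aa in c("GLY", "TRP", "HIS")) {
    v <- one_hot_aa(aa)
    expect_equal(sum(v), 1)
    expect_true(all(v %in% c(0, 1)))
  }
  expect_error(one_hot_aa("XYZ"), "unknown residue")
})

test_that("positional encoding matches the sinusoid definition", {
  pe0 <- positional_encoding(0L, 12L)
  expect_equal(pe0[1, seq(1, 11, by = 2)], rep(0, 6))
  expect_equal(pe0[1, seq(2, 12, by = 2)], rep(1, 6))
  pe1 <- positional_encoding(1L, 12L)
  expect_equal(pe1[1, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe1[1, 3], sin(1 / 10000^(2 / 12)), tolerance = 1e-12)
  pe_many <- positional_encoding(0:200, 12L)
  expect_true(all(pe_many >= -1 & pe_many <= 1))
  expect_error(positional_encoding(1L, 7L), "even")
})

make_residue <- function(n, ca, cb, aa = "ALA") {
  list(aa = aa, atoms = list(N = n, CA = ca, C = ca + c(1.5, 0, 0),
                             CB = cb))
}

test_that("edge geometry is symmetric in the documented pattern", {
  set.seed(11)
  ri <- make_residue(rnorm(3), rnorm(3), rnorm(3) + 3)
  rj <- make_residue(rnorm(3) + 5, rnorm(3) + 5, rnorm(3) + 6)
  gij <- edge_geometry(ri, rj)
  gji <- edge_geometry(rj, ri)
  expect_equal(gij[["d"]], gji[["d"]])
  expect_equal(gij[["alpha"]], gji[["alpha"]])
  expect_equal(abs(gij[["omega"]]), abs(gji[["omega"]]), tolerance = 1e-9)
  expect_equal(gij[["theta_ij"]], gji[["theta_ji"]])
  expect_equal(gij[["theta_ji"]], gji[["theta_ij"]])
  expect_equal(gij[["phi_ij"]], gji[["phi_ji"]])
  expect_equal(gij[["phi_ji"]], gji[["phi_ij"]])
})

test_that("hand-placed coordinates give the expected dihedrals", {
  # omega frame CAi=(0,0,0), CBi=(1,0,0), CBj=(1,1,0), CAj=(1,1,1)
  ri <- list(aa = "ALA", atoms = list(N = c(0, -1, 0), CA = c(0, 0, 0),
                                      C = c(0.5, -1, 0), CB = c(1, 0, 0)))
  rj <- list(aa = "ALA", atoms = list(N = c(2, 1, 1), CA = c(1, 1, 1),
                                      C = c(1, 2, 1), CB = c(1, 1, 0)))
  g <- edge_geometry(ri, rj)
  expect_equal(abs(g[["omega"]]), pi / 2, tolerance = 1e-12)
  # coplanar omega frame collapses to 0 or pi
  rj2 <- rj
  rj2$atoms$CA <- c(2, 1, 0)  # all four atoms in the z=0 plane
  g2 <- edge_geometry(ri, rj2)
  expect_true(min(abs(g2[["omega"]]), abs(abs(g2[["omega"]]) - pi)) < 1e-9)
})

test_that("node matrix is 83 wide and edge matrix 10 wide", {
  s <- toy_dimer(seed = 12L, chain_length = 9L)
  g <- build_graph(s)
  nx <- assemble_node_features(s)
  ex <- assemble_edge_features(g, s)
  expect_equal(ncol(nx), 83L)
  expect_equal(nrow(nx), n_residues_of(s))
  expect_equal(ncol(ex), 10L)
  expect_equal(nrow(ex), nrow(g$edges))
  expect_equal(sum(node_feature_layout()), 83L)
})

test_that("featurization is deterministic and zero-provider mode works", {
  s <- toy_dimer(seed = 13L, chain_length = 7L)
  g <- build_graph(s)
  expect_identical(assemble_node_features(s), assemble_node_features(s))
  expect_identical(assemble_edge_features(g, s),
                   assemble_edge_features(g, s))
  nx0 <- assemble_node_features(s, providers = list())
  expect_equal(ncol(nx0), 83L)
  expect_true(all(nx0[, grep("^pssm", colnames(nx0))] == 0))
  expect_true(all(rowSums(nx0[, grep("^one_hot", colnames(nx0))]) == 1))
  expect_true(any(nx0[, grep("^positional", colnames(nx0))] != 0))
})

test_that("provider width mismatch is reported with the block name", {
  s <- toy_dimer(seed = 13L, chain_length = 7L)
  bad <- default_providers()
  bad$pssm <- synthetic_provider("pssm", 7L)
  expect_error(assemble_node_features(s, bad), "pssm")
})

test_that("interface potentials are gated to cross-chain edges", {
  s <- toy_dimer(seed = 14L, chain_length = 10L)
  g <- build_graph(s)
  ex <- assemble_edge_features(g, s)
  pot <- c("cdp", "rsap_i", "rsap_j")
  intra <- !g$cross_chain_mask
  expect_true(all(ex[intra, pot] == 0))
  expect_true(any(g$cross_chain_mask))
  expect_true(all(ex[g$cross_chain_mask, "cdp"] != 0))
})

test_that("geometric edge features are rigid-motion invariant", {
  s <- toy_dimer(seed = 15L, chain_length = 10L)
  g <- build_graph(s)
  ex <- assemble_edge_features(g, s)
  s2 <- rigidly_move(s, seed = 21L)
  g2 <- build_graph(s2)
  ex2 <- assemble_edge_features(g2, s2)
  expect_identical(unname(g2$edges), unname(g$edges))
  geom <- c("d", "alpha", "omega", "theta_ij", "theta_ji", "phi_ij",
            "phi_ji")
  expect_equal(ex2[, geom], ex[, geom], tolerance = 1e-6)
})

test_that("embedding summary rows are the column statistics", {
  const <- matrix(0.37, 5L, 4L)
  sm <- meqa:::summary_rows(const)
  expect_equal(unname(sm["mean", ]), rep(0.37, 4))
  expect_equal(unname(sm["median", ]), rep(0.37, 4))
  expect_equal(unname(sm["sd", ]), rep(0, 4))
  expect_equal(unname(sm["var", ]), rep(0, 4))
  s <- toy_dimer(seed = 16L, chain_length = 6L)
  nx <- assemble_node_features(s, esm_width = 4L)
  expect_equal(ncol(nx), 83L + 5L * 4L)
  expect_equal(attr(nx, "core_width"), 83L)
  eb <- esm_block(s, 4L)
  expect_equal(unname(nx[1, "esm_mean.1"]),
               unname(mean(eb$embedding[, 1])))
})
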