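# Shared fixtures and independent oracles, all built in code.

n_residues_of <- function(s) nrow(s$residues)

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Small deterministic dimer used across tests.
toy_dimer <- function(seed = 3L, chain_length = 10L, n_chains = 2L) {
  generate_toy_complex(decoy_spec(n_chains = n_chains,
                                  chain_length = chain_length,
                                  seed = seed))
}

# O(n^2) all-pairs contact oracle over representative atoms.
brute_force_edges <- function(s, cutoff = 8.0) {
  xyz <- meqa:::representative_coords(s)
  D <- as.matrix(stats::dist(xyz))
  hits <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  m <- cbind(hits[, 1], hits[, 2])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Cross-chain interface oracle: direct distance scan.
brute_force_interface <- function(s, cutoff = 8.0) {
  xyz <- meqa:::representative_coords(s)
  ch <- s$residues$chain
  D <- as.matrix(stats::dist(xyz))
  vapply(seq_len(nrow(xyz)), function(i) {
    any(D[i, ] <= cutoff & ch != ch[i])
  }, logical(1))
}

# Naive contrastive loss without the log-sum-exp trick.
naive_nce_loss <- function(scores, log_densities) {
  a <- exp(scores - log_densities)
  -mean(log(a[, 1] / rowSums(a)))
}

# A hand-built graph input: n nodes with given coordinates-free features.
tiny_graph_input <- function(node_x, edges, edge_x) {
  if (nrow(edges)) {
    src <- c(edges[, 1], edges[, 2]); dst <- c(edges[, 2], edges[, 1])
    ex <- rbind(edge_x, edge_x)
  } else {
    src <- integer(0); dst <- integer(0); ex <- edge_x
  }
  list(node_x = node_x, src = src, dst = dst, edge_x = ex,
       n = nrow(node_x))
}

# Permute the nodes of a graph input (relabelling endpoints to match).
permute_graph_input <- function(gd, perm) {
  remap <- integer(gd$n)
  remap[perm] <- seq_len(gd$n)
  list(node_x = gd$node_x[perm, , drop = FALSE],
       src = remap[gd$src], dst = remap[gd$dst],
       edge_x = gd$edge_x, n = gd$n)
}

# Random rigid motion applied to a whole structure.
rigidly_move <- function(s, seed = 1L) {
  set.seed(seed)
  meqa:::transform_structure(s, meqa:::random_rotation(180),
                             stats::rnorm(3, sd = 10))
}
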