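# Synthetic data: toy multi-chain helical complexes, graded decoys made by
# rigid-body perturbation plus atomic jitter, stand-in quality labels
# (fold: Kabsch superposition + TM-style distance scoring with fixed
# residue correspondence; interface: Jaccard overlap of cross-chain
# contact sets), and embedding datasets for exercising the energy-based
# regressor. Everything is deterministic given its seed.

#' Decoy generation settings
#'
#' @param n_chains number of chains (>= 2 for multimer work)
#' @param chain_length residues per chain (>= 4)
#' @param rigid_rotation_max per-chain rotation bound, degrees
#' @param rigid_translation_max per-chain translation bound, Angstrom
#' @param jitter_sd per-coordinate Gaussian jitter, Angstrom
#' @param separation distance between adjacent chain axes, Angstrom
#' @param seed RNG seed; fully determines all generated output
#' @return a `DecoySpec` list
#' @export
decoy_spec <- function(n_chains = 2L, chain_length = 20L,
                       rigid_rotation_max = 10, rigid_translation_max = 2,
                       jitter_sd = 0.2, separation = 9, seed = 1L) {
  stopifnot(n_chains >= 1L, chain_length >= 4L, rigid_rotation_max >= 0,
            rigid_translation_max >= 0, jitter_sd >= 0, separation > 0)
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 rigid_rotation_max = rigid_rotation_max,
                 rigid_translation_max = rigid_translation_max,
                 jitter_sd = jitter_sd, separation = separation,
                 seed = as.integer(seed)),
            class = "DecoySpec")
}

# Ideal-geometry helical backbone for one chain: cylindrical coordinates
# per atom type (radius, phase offset, rise offset), 100 degrees and
# 1.5 A per residue. CB is reconstructed virtually from N, CA, C.
helix_chain <- function(chain_id, length, aa, origin = c(0, 0, 0)) {
  k <- seq_len(length) - 1L
  par <- list(n = c(1.58, -27.6 * pi / 180, -0.70),
              ca = c(2.27, 0, 0),
              c = c(1.99, 27.0 * pi / 180, 0.55))
  phase <- k * 100 * pi / 180
  rise <- k * 1.5
  df <- data.frame(chain = chain_id, seq_pos = k + 1L, aa = aa)
  for (at in names(par)) {
    p <- par[[at]]
    df[[paste0(at, "_x")]] <- p[1] * cos(phase + p[2]) + origin[1]
    df[[paste0(at, "_y")]] <- p[1] * sin(phase + p[2]) + origin[2]
    df[[paste0(at, "_z")]] <- rise + p[3] + origin[3]
  }
  df
}

#' Generate a toy multimeric complex
#'
#' Parallel ideal helices, one per chain, placed on a circle so adjacent
#' chains share an interface at the default contact cutoff. Amino acids
#' are sampled per residue (glycine included). If a placement yields no
#' cross-chain contact, the chains are moved closer and rebuilt.
#'
#' @param spec a [decoy_spec()]
#' @return a `ComplexStructure` (deterministic per seed)
#' @export
generate_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "DecoySpec"))
  set.seed(spec$seed)
  aa <- replicate(spec$n_chains,
                  sample(AA3, spec$chain_length, replace = TRUE),
                  simplify = FALSE)
  sep <- spec$separation
  repeat {
    chains <- lapply(seq_len(spec$n_chains), function(ci) {
      if (spec$n_chains == 1L) {
        origin <- c(0, 0, 0)
      } else {
        r <- sep / (2 * sin(pi / spec$n_chains))
        ang <- 2 * pi * (ci - 1L) / spec$n_chains
        origin <- c(r * cos(ang), r * sin(ang), 0)
      }
      helix_chain(LETTERS[ci], spec$chain_length, aa[[ci]], origin)
    })
    s <- complex_structure(do.call(rbind, chains),
                           model_id = sprintf("toy_c%d_l%d_s%d",
                                              spec$n_chains,
                                              spec$chain_length,
                                              spec$seed))
    if (spec$n_chains == 1L) return(s)
    g <- build_graph(s)
    if (any(g$cross_chain_mask)) return(s)
    sep <- sep - 1
    if (sep <= 4) stop("could not place chains in contact")
  }
}

#' Perturb a structure into a decoy
#'
#' Each chain receives an independent random rigid-body motion (rotation
#' about its centroid up to `rigid_rotation_max` degrees, translation up
#' to `rigid_translation_max` Angstrom) followed by i.i.d. Gaussian jitter
#' on every backbone coordinate. Virtual CBs are rebuilt from the
#' perturbed backbone. Uses the caller's RNG stream.
#'
#' @param native a `ComplexStructure`
#' @param spec a [decoy_spec()] providing the magnitudes
#' @param scale optional factor in [0,1] scaling all magnitudes (graded
#'   decoy quality)
#' @param model_id identifier for the decoy
#' @return a perturbed `ComplexStructure`
#' @export
perturb_decoy <- function(native, spec, scale = 1,
                          model_id = paste0(native$model_id, "_decoy")) {
  res <- native$residues
  coord_cols <- paste0(rep(c("n", "ca", "c"), each = 3), "_",
                       c("x", "y", "z"))
  for (ch in native$chain_ids) {
    sel <- res$chain == ch
    xyz <- as.matrix(res[sel, coord_cols])
    pts <- rbind(xyz[, 1:3], xyz[, 4:6], xyz[, 7:9])
    centroid <- colMeans(pts)
    R <- random_rotation(spec$rigid_rotation_max * scale)
    dirv <- stats::rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    tr <- dirv * stats::runif(1, 0, spec$rigid_translation_max * scale)
    move <- function(m) {
      sweep(sweep(m, 2L, centroid) %*% t(R), 2L, centroid + tr, "+")
    }
    for (blk in list(1:3, 4:6, 7:9)) {
      xyz[, blk] <- move(xyz[, blk, drop = FALSE])
    }
    jit <- spec$jitter_sd * scale
    if (jit > 0) xyz <- xyz + stats::rnorm(length(xyz), 0, jit)
    res[sel, coord_cols] <- xyz
  }
  res$cb_x <- NA_real_; res$cb_y <- NA_real_; res$cb_z <- NA_real_
  complex_structure(res[, c("chain", "seq_pos", "aa", coord_cols)],
                    model_id = model_id)
}

# Optimal rotation (Kabsch, via SVD) aligning centred P onto centred Q.
kabsch_rotation <- function(P0, Q0) {
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Stand-in overall-fold quality label
#'
#' TM-style score with fixed residue correspondence: least-squares rigid
#' superposition (Kabsch) of the decoy's CA trace onto the native, then
#' `mean(1 / (1 + (d_i/d0)^2))` with `d0 = 1.24 (L-15)^(1/3) - 1.8`
#' floored at 0.5 Angstrom. No alignment search is performed; this is a
#' documented stand-in for TM-score, not the official program.
#'
#' @param native,decoy `ComplexStructure`s with identical residue lists
#' @return score in (0, 1]; exactly 1 for a rigidly moved copy
#' @export
fold_label <- function(native, decoy) {
  if (n_residues(native) != n_residues(decoy)) {
    stop("native and decoy differ in length")
  }
  ca <- c("ca_x", "ca_y", "ca_z")
  P <- as.matrix(decoy$residues[, ca])
  Q <- as.matrix(native$residues[, ca])
  P0 <- sweep(P, 2L, colMeans(P))
  Q0 <- sweep(Q, 2L, colMeans(Q))
  R <- kabsch_rotation(P0, Q0)
  d <- row_norm(P0 %*% R - Q0)
  mean(1 / (1 + (d / tm_d0(nrow(P)))^2))
}

# Length-dependent distance scale of the TM-style score, floored at 0.5 A.
tm_d0 <- function(L) {
  if (L > 15L) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8) else 0.5
}

# Cross-chain contact pairs at the cutoff, as "i:j" keys.
cross_contacts <- function(s, cutoff = 8.0) {
  g <- build_graph(s, cutoff)
  e <- g$edges[g$cross_chain_mask, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  paste(e[, 1], e[, 2], sep = ":")
}

#' Stand-in interface quality label
#'
#' Jaccard overlap of the cross-chain residue contact sets (representative
#' atoms within the cutoff) of native and decoy: shared contacts over the
#' union. A documented stand-in for interface similarity scores such as
#' QS-score, not the official program.
#'
#' @param native,decoy `ComplexStructure`s with identical chains/lengths
#' @param cutoff contact cutoff in Angstrom
#' @return score in [0, 1]
#' @export
interface_label <- function(native, decoy, cutoff = 8.0) {
  if (n_residues(native) != n_residues(decoy)) {
    stop("native and decoy differ in length")
  }
  cn <- cross_contacts(native, cutoff)
  if (!length(cn)) stop("native structure has no cross-chain contacts")
  cd <- cross_contacts(decoy, cutoff)
  length(intersect(cn, cd)) / length(union(cn, cd))
}

#' Generate a labelled decoy set
#'
#' Builds the native toy complex for `spec`, then `n_decoys` perturbed
#' copies with graded magnitudes (`scale` drawn uniformly in [0,1] per
#' decoy) and computes both stand-in quality labels.
#'
#' @param spec a [decoy_spec()]
#' @param n_decoys number of decoys
#' @return list with `native`, `decoys` (list of `ComplexStructure`) and
#'   `labels` (data.frame: model_id, scale, fold_label, interface_label)
#' @export
make_labeled_decoy_set <- function(spec, n_decoys = 20L) {
  native <- generate_toy_complex(spec)
  set.seed(spec$seed + 1L)
  decoys <- vector("list", n_decoys)
  lab <- data.frame(model_id = character(n_decoys), scale = numeric(n_decoys),
                    fold_label = numeric(n_decoys),
                    interface_label = numeric(n_decoys))
  for (k in seq_len(n_decoys)) {
    sc <- stats::runif(1)
    dk <- perturb_decoy(native, spec, scale = sc,
                        model_id = sprintf("%s_d%03d", native$model_id, k))
    decoys[[k]] <- dk
    lab$model_id[k] <- dk$model_id
    lab$scale[k] <- sc
    lab$fold_label[k] <- fold_label(native, dk)
    lab$interface_label[k] <- interface_label(native, dk)
  }
  list(native = native, decoys = decoys, labels = lab)
}

#' Synthetic embedding dataset for the energy-based regressor
#'
#' Embeddings are i.i.d. standard normal; the score is a logistic-linear
#' function of the embedding through a hidden weight vector, plus optional
#' bounded noise (Gaussian truncated at 3 sd) added in logit space, then
#' clamped into (0,1). The hidden mapping is returned for
#' parameter-recovery tests.
#'
#' @param n number of examples
#' @param width embedding width (>= 2)
#' @param noise_sd logit-space noise standard deviation
#' @param seed RNG seed
#' @return list with `X` (n x width), `score` (length n), and the hidden
#'   `w`, `b`
#' @export
make_embedding_dataset <- function(n, width = 16L, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(width >= 2L)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * width), n, width)
  w <- stats::rnorm(width, sd = 2 / sqrt(width))
  b <- 0
  lin <- drop(X %*% w) + b
  if (noise_sd > 0) {
    eps <- stats::rnorm(n, 0, noise_sd)
    lin <- lin + pmin(pmax(eps, -3 * noise_sd), 3 * noise_sd)
  }
  score <- pmin(pmax(stats::plogis(lin), 1e-4), 1 - 1e-4)
  list(X = X, score = score, w = w, b = b)
}

#' Synthetic graph dataset with a known graph-statistic label
#'
#' Generates toy dimer complexes with varying chain separations and labels
#' each graph with the fraction of interface residues (clamped into
#' (0.01, 0.99)), a statistic a backbone can recover from the
#' interface-gated edge features. Used for backbone parameter-recovery
#' tests.
#'
#' @param n_graphs number of graphs
#' @param n_chains,chain_length toy complex size
#' @param providers feature providers (default synthetic set)
#' @param seed RNG seed
#' @return list with `graphs` (list of [graph_input()]), `labels`, and
#'   `separations`
#' @export
make_graph_label_dataset <- function(n_graphs, n_chains = 2L,
                                     chain_length = 12L,
                                     providers = default_providers(),
                                     seed = 1L) {
  set.seed(seed)
  seps <- stats::runif(n_graphs, 6.2, 11.5)
  graph_seeds <- sample.int(1e6, n_graphs)
  graphs <- vector("list", n_graphs)
  labels <- numeric(n_graphs)
  for (k in seq_len(n_graphs)) {
    sp <- decoy_spec(n_chains = n_chains, chain_length = chain_length,
                     separation = seps[k], seed = graph_seeds[k])
    s <- tryCatch(generate_toy_complex(sp), error = function(e) NULL)
    if (is.null(s)) {
      sp <- decoy_spec(n_chains = n_chains, chain_length = chain_length,
                       separation = 8, seed = graph_seeds[k])
      s <- generate_toy_complex(sp)
    }
    g <- build_graph(s)
    nx <- assemble_node_features(s, providers)
    ex <- assemble_edge_features(g, s, providers)
    graphs[[k]] <- graph_input(g, nx, ex)
    labels[k] <- min(max(mean(g$interface_mask), 0.01), 0.99)
  }
  list(graphs = graphs, labels = labels, separations = seps)
}

#' Write a decoy set to disk
#'
#' PDB file per structure plus a labels TSV (model_id, fold_label,
#' interface_label).
#'
#' @param dset a [make_labeled_decoy_set()] result
#' @param dir output directory (created if needed)
#' @return the labels TSV path, invisibly
#' @export
write_decoy_set <- function(dset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb_complex(dset$native,
                    file.path(dir, paste0(dset$native$model_id, ".pdb")))
  for (d in dset$decoys) {
    write_pdb_complex(d, file.path(dir, paste0(d$model_id, ".pdb")))
  }
  path <- file.path(dir, "labels.tsv")
  utils::write.table(dset$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
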