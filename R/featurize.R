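# Node and edge featurization. Node features follow a fixed 83-wide layout
# of six blocks; edge features are ten values from five types (distance,
# inter-residue angle, three dihedral/planar orientation angles in both
# directions, and two interface-gated statistical potentials). Features
# normally produced by external tools (PSSM, energy terms, secondary
# structure agreement, statistical potentials) enter through a provider
# contract; the shipped default providers are deterministic synthetic
# stand-ins so the pipeline runs with no external binaries.

#' Node feature layout
#'
#' @return named integer vector of block widths, in fixed order, summing
#'   to 83: one-hot amino acid (20), PSSM (20), per-residue energy terms
#'   (20), secondary-structure/solvent agreement scores (5), sinusoidal
#'   positional encoding (12), statistical potentials (6)
#' @export
node_feature_layout <- function() {
  c(one_hot = 20L, pssm = 20L, energy_terms = 20L, sov_scores = 5L,
    positional_encoding = 12L, mass_potentials = 6L)
}

#' Edge feature names
#'
#' @return character vector of the 10 edge feature columns
#' @export
edge_feature_names <- function() {
  c("d", "alpha", "omega", "theta_ij", "theta_ji", "phi_ij", "phi_ji",
    "cdp", "rsap_i", "rsap_j")
}

#' One-hot encoding of an amino acid
#'
#' @param aa three-letter code of a standard residue
#' @return length-20 0/1 vector in the fixed alphabetical-by-code ordering
#' @export
one_hot_aa <- function(aa) {
  i <- match(toupper(aa), AA3)
  if (is.na(i)) stop("unknown residue code: ", aa)
  v <- numeric(20L)
  v[i] <- 1
  v
}

#' Sinusoidal positional encoding
#'
#' Entry `2i` is `sin(pos / 10000^(2i/width))` and entry `2i+1` the
#' matching cosine (`i` 0-based). Positions index the concatenated
#' multi-chain sequence, 0-based.
#'
#' @param seq_pos 0-based position (vectorised)
#' @param width even output width (default 12)
#' @return matrix `length(seq_pos)` x `width`
#' @export
positional_encoding <- function(seq_pos, width = 12L) {
  if (width %% 2L != 0L) stop("positional encoding width must be even")
  stopifnot(all(seq_pos >= 0))
  i <- seq_len(width %/% 2L) - 1L
  freq <- 1 / 10000^(2 * i / width)
  arg <- outer(seq_pos, freq)
  out <- matrix(0, length(seq_pos), width)
  out[, 2L * i + 1L] <- sin(arg)
  out[, 2L * i + 2L] <- cos(arg)
  out
}

## ---- vector geometry -----------------------------------------------------

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

# Planar angle at b formed by a-b-c, rowwise, in [0, pi]; 0 on degenerate
# (zero-length) arms.
angle_rows <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- row_norm(u); nv <- row_norm(v)
  bad <- nu < 1e-9 | nv < 1e-9
  cosang <- pmin(pmax(row_dot(u, v) / pmax(nu * nv, 1e-12), -1), 1)
  out <- acos(cosang)
  if (any(bad)) {
    warning("degenerate planar angle set to 0")
    out[bad] <- 0
  }
  out
}

# Signed dihedral p1-p2-p3-p4, rowwise, right-hand rule, in (-pi, pi];
# 0 on degenerate frames.
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  bad <- row_norm(n1) < 1e-9 | row_norm(n2) < 1e-9 | nb2 < 1e-9
  m1 <- row_cross(n1, b2 / pmax(nb2, 1e-12))
  x <- row_dot(n1, n2)
  y <- row_dot(m1, n2)
  out <- atan2(y, x)
  out[out <= -pi] <- pi
  if (any(bad)) {
    warning("degenerate dihedral set to 0")
    out[bad] <- 0
  }
  out
}

#' Geometric features of a residue pair
#'
#' Computes the seven orientation features of an edge i-j: the CB-CB
#' distance `d`; `alpha`, the angle between the CA->CB vectors of the two
#' residues; the dihedral `omega` (CAi, CBi, CBj, CAj); the dihedrals
#' `theta_ij` (Ni, CAi, CBi, CBj) and `theta_ji`; and the planar angles
#' `phi_ij` (CAi, CBi, CBj) and `phi_ji`. Glycine uses its virtual CB.
#'
#' @param ri,rj residue records from [get_residue()]
#' @return named numeric vector of length 7
#' @export
edge_geometry <- function(ri, rj) {
  gi <- lapply(ri$atoms, function(v) matrix(v, 1L))
  gj <- lapply(rj$atoms, function(v) matrix(v, 1L))
  d <- row_norm(gi$CB - gj$CB)
  z <- matrix(0, 1L, 3L)
  c(d = d,
    alpha = angle_rows(gi$CB - gi$CA, z, gj$CB - gj$CA),
    omega = dihedral_rows(gi$CA, gi$CB, gj$CB, gj$CA),
    theta_ij = dihedral_rows(gi$N, gi$CA, gi$CB, gj$CB),
    theta_ji = dihedral_rows(gj$N, gj$CA, gj$CB, gi$CB),
    phi_ij = angle_rows(gi$CA, gi$CB, gj$CB),
    phi_ji = angle_rows(gj$CA, gj$CB, gi$CB))
}

## ---- providers -----------------------------------------------------------

# Deterministic integer hash of a string, in [0, 2^31).
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic pseudo-uniform value in (-1, 1) from a string key.
hash_unit <- function(x) 2 * (string_hash(x) / 2147483647) - 1

#' Synthetic per-residue feature provider
#'
#' Stand-in for an external feature tool. Values are a deterministic hash
#' of (provider name, seed, chain, position, amino acid, column), so the
#' same structure always featurizes identically and different residues or
#' providers decorrelate. Width and name follow the layout block filled.
#'
#' @param name provider/block name
#' @param width number of columns produced per residue
#' @param seed integer mixed into the hash
#' @return a `FeatureProvider`: list with `name`, `width`, and
#'   `per_residue(structure)` returning an n x width matrix
#' @export
synthetic_provider <- function(name, width, seed = 1L) {
  force(name); force(width); force(seed)
  structure(list(
    name = name, width = width,
    per_residue = function(s) {
      r <- s$residues
      keys <- paste(name, seed, r$chain, r$seq_pos, r$aa, sep = "|")
      out <- matrix(0, nrow(r), width)
      for (k in seq_len(width)) {
        out[, k] <- hash_unit(paste(keys, k, sep = "|"))
      }
      out
    }), class = "FeatureProvider")
}

#' Synthetic residue-pair potential provider
#'
#' Deterministic stand-in for pairwise statistical potentials (e.g. a
#' contact-dependent potential). Symmetric in the pair by construction.
#'
#' @inheritParams synthetic_provider
#' @return list with `name` and `per_pair(structure, i, j)` returning one
#'   value per pair (i, j vectors of global residue indices)
#' @export
synthetic_pair_provider <- function(name, seed = 1L) {
  force(name); force(seed)
  structure(list(
    name = name,
    per_pair = function(s, i, j) {
      r <- s$residues
      a <- pmin(i, j); b <- pmax(i, j)
      hash_unit(paste(name, seed, r$chain[a], r$seq_pos[a], r$chain[b],
                      r$seq_pos[b], sep = "|"))
    }), class = "FeatureProvider")
}

#' Default synthetic provider set
#'
#' One provider per externally sourced layout block, plus the pair
#' potential (`cdp`) and per-residue solvent-accessibility potential
#' (`rsap`) used on interface edges.
#'
#' @param seed integer seed mixed into every provider hash
#' @return named list of providers
#' @export
default_providers <- function(seed = 1L) {
  list(pssm = synthetic_provider("pssm", 20L, seed),
       energy_terms = synthetic_provider("energy_terms", 20L, seed),
       sov_scores = synthetic_provider("sov_scores", 5L, seed),
       mass_potentials = synthetic_provider("mass_potentials", 6L, seed),
       cdp = synthetic_pair_provider("cdp", seed),
       rsap = synthetic_provider("rsap", 1L, seed))
}

#' Synthetic sequence-embedding block
#'
#' Stand-in for a learned language-model embedding: a deterministic
#' per-residue matrix plus its column-wise mean, median, standard
#' deviation and variance summary rows. The block is optional and never
#' counted in the 83 core node features.
#'
#' @param s a `ComplexStructure`
#' @param width embedding width
#' @param seed hash seed
#' @return list with `embedding` (n x width) and `summary` (4 x width,
#'   rows mean/median/sd/var)
#' @export
esm_block <- function(s, width = 8L, seed = 1L) {
  emb <- synthetic_provider("esm", width, seed)$per_residue(s)
  list(embedding = emb, summary = summary_rows(emb))
}

# Column-wise mean/median/sd/var summary rows of a per-residue matrix.
summary_rows <- function(m) {
  rbind(mean = colMeans(m),
        median = apply(m, 2L, stats::median),
        sd = apply(m, 2L, stats::sd),
        var = apply(m, 2L, stats::var))
}

## ---- assembly ------------------------------------------------------------

#' Assemble the node feature matrix
#'
#' Fills the fixed 83-wide layout: one-hot residue identity and the
#' positional encoding are computed internally; the remaining blocks come
#' from the registered providers (zero-filled when a provider is absent).
#' When `esm_width > 0` the synthetic embedding block (per-residue values
#' plus broadcast summary statistics) is appended after the core 83.
#'
#' @param s a `ComplexStructure`
#' @param providers named provider list as from [default_providers()];
#'   `NULL` entries give zero-filled blocks
#' @param esm_width optional embedding width (0 = no embedding block)
#' @param esm_seed hash seed for the embedding block
#' @return numeric matrix n x 83 (+ 5*esm_width) with named columns; the
#'   core width is recorded in `attr(, "core_width")`
#' @export
assemble_node_features <- function(s, providers = default_providers(),
                                   esm_width = 0L, esm_seed = 1L) {
  layout <- node_feature_layout()
  r <- s$residues
  n <- nrow(r)
  blocks <- list()
  blocks$one_hot <- t(vapply(r$aa, one_hot_aa, numeric(20L)))
  colnames(blocks$one_hot) <- paste0("one_hot.", AA3)
  for (nm in c("pssm", "energy_terms", "sov_scores", "mass_potentials")) {
    p <- providers[[nm]]
    if (is.null(p)) {
      blocks[[nm]] <- matrix(0, n, layout[[nm]])
    } else {
      m <- p$per_residue(s)
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != layout[[nm]]) {
        stop("provider for block '", nm, "' returned wrong shape: ",
             "expected ", n, " x ", layout[[nm]])
      }
      blocks[[nm]] <- m
    }
    colnames(blocks[[nm]]) <- paste0(nm, ".", seq_len(layout[[nm]]))
  }
  pe <- positional_encoding(seq_len(n) - 1L,
                            layout[["positional_encoding"]])
  colnames(pe) <- paste0("positional_encoding.",
                         seq_len(layout[["positional_encoding"]]))
  blocks$positional_encoding <- pe
  out <- do.call(cbind, blocks[names(layout)])
  stopifnot(ncol(out) == sum(layout))
  if (esm_width > 0L) {
    eb <- esm_block(s, esm_width, esm_seed)
    broad <- matrix(t(eb$summary), n, 4L * esm_width, byrow = TRUE)
    extra <- cbind(eb$embedding, broad)
    colnames(extra) <- c(paste0("esm.", seq_len(esm_width)),
                         paste0(rep(c("esm_mean.", "esm_median.",
                                      "esm_sd.", "esm_var."),
                                    each = esm_width), seq_len(esm_width)))
    out <- cbind(out, extra)
  }
  attr(out, "core_width") <- sum(layout)
  out
}

#' Assemble the edge feature matrix
#'
#' Ten features per edge: the seven geometric features from
#' [edge_geometry()] (always present) and the contact-dependent potential
#' plus the two endpoint solvent-accessibility potentials, populated from
#' providers only when the edge crosses chains (zero otherwise).
#'
#' @param g a `ResidueGraph` built from `s`
#' @param s the matching `ComplexStructure`
#' @param providers provider list (needs `cdp` and `rsap` for interface
#'   edges; `NULL` entries give zeros)
#' @return numeric matrix (n edges) x 10, columns [edge_feature_names()]
#' @export
assemble_edge_features <- function(g, s, providers = default_providers()) {
  stopifnot(inherits(g, "ResidueGraph"), inherits(s, "ComplexStructure"))
  e <- g$edges
  m <- nrow(e)
  out <- matrix(0, m, 10L, dimnames = list(NULL, edge_feature_names()))
  if (m == 0L) return(out)
  r <- s$residues
  P <- function(cols) as.matrix(r[, cols])
  N <- P(c("n_x", "n_y", "n_z")); CA <- P(c("ca_x", "ca_y", "ca_z"))
  CB <- P(c("cb_x", "cb_y", "cb_z"))
  i <- e[, 1]; j <- e[, 2]
  out[, "d"] <- row_norm(CB[i, , drop = FALSE] - CB[j, , drop = FALSE])
  # alpha: angle between the two CA->CB vectors (translated to a shared
  # vertex so angle_rows applies)
  ui <- CB[i, , drop = FALSE] - CA[i, , drop = FALSE]
  uj <- CB[j, , drop = FALSE] - CA[j, , drop = FALSE]
  z <- matrix(0, m, 3L)
  out[, "alpha"] <- angle_rows(ui, z, uj)
  out[, "omega"] <- dihedral_rows(CA[i, , drop = FALSE],
                                  CB[i, , drop = FALSE],
                                  CB[j, , drop = FALSE],
                                  CA[j, , drop = FALSE])
  out[, "theta_ij"] <- dihedral_rows(N[i, , drop = FALSE],
                                     CA[i, , drop = FALSE],
                                     CB[i, , drop = FALSE],
                                     CB[j, , drop = FALSE])
  out[, "theta_ji"] <- dihedral_rows(N[j, , drop = FALSE],
                                     CA[j, , drop = FALSE],
                                     CB[j, , drop = FALSE],
                                     CB[i, , drop = FALSE])
  out[, "phi_ij"] <- angle_rows(CA[i, , drop = FALSE],
                                CB[i, , drop = FALSE],
                                CB[j, , drop = FALSE])
  out[, "phi_ji"] <- angle_rows(CA[j, , drop = FALSE],
                                CB[j, , drop = FALSE],
                                CB[i, , drop = FALSE])
  cross <- g$cross_chain_mask
  if (any(cross)) {
    if (!is.null(providers$cdp)) {
      out[cross, "cdp"] <- providers$cdp$per_pair(s, i[cross], j[cross])
    }
    if (!is.null(providers$rsap)) {
      rs <- providers$rsap$per_residue(s)
      out[cross, "rsap_i"] <- rs[i[cross], 1L]
      out[cross, "rsap_j"] <- rs[j[cross], 1L]
    }
  }
  out
}

#' Write a feature matrix as TSV
#'
#' @param x feature matrix with column names
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
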