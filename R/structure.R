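# Parsing multimeric model structures into a flat residue table and the
# geometry helpers (representative atoms, virtual CB) the graph and feature
# code builds on.

# The 20 standard residues, alphabetical by three-letter code. This fixed
# ordering defines the one-hot feature layout.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Common non-standard residues mapped to their standard parents; anything
# not standard and not in this table is dropped with a warning.
AA_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
               MLY = "LYS", CSO = "CYS", SEP = "SER", TPO = "THR",
               PTR = "TYR", HSD = "HIS", HSE = "HIS", HSP = "HIS",
               CYX = "CYS", HID = "HIS", HIE = "HIS", HIP = "HIS")

map_residue_name <- function(aa) {
  aa <- toupper(aa)
  out <- ifelse(aa %in% AA3, aa, unname(AA_PARENT[aa]))
  out
}

#' Construct a complex structure from a residue table
#'
#' The canonical in-memory form of a multi-chain model: one row per residue
#' with backbone (N, CA, C) and CB coordinates. A virtual CB is
#' reconstructed from N, CA, C by ideal tetrahedral geometry wherever the
#' real atom is absent (always for glycine); `cb_virtual` records this.
#'
#' @param residues data.frame with columns `chain`, `seq_pos`, `aa` and
#'   coordinate columns `n_x..cb_z` (`cb_*` may be NA; filled virtually)
#' @param model_id identifier carried through scoring tables
#' @return a `ComplexStructure`
#' @export
complex_structure <- function(residues, model_id = "model") {
  need <- c("chain", "seq_pos", "aa",
            paste0(rep(c("n", "ca", "c"), each = 3), "_", c("x", "y", "z")))
  stopifnot(all(need %in% names(residues)))
  residues$aa <- map_residue_name(residues$aa)
  if (anyNA(residues$aa)) stop("unmappable residue names in input")
  cbc <- paste0("cb_", c("x", "y", "z"))
  if (!all(cbc %in% names(residues))) residues[cbc] <- NA_real_
  miss <- is.na(residues$cb_x) | residues$aa == "GLY"
  residues$cb_virtual <- miss
  if (any(miss)) {
    vcb <- virtual_cb(as.matrix(residues[miss, c("n_x", "n_y", "n_z")]),
                      as.matrix(residues[miss, c("ca_x", "ca_y", "ca_z")]),
                      as.matrix(residues[miss, c("c_x", "c_y", "c_z")]))
    residues[miss, cbc] <- vcb
  }
  co <- as.matrix(residues[, c(need[-(1:3)], cbc)])
  if (!all(is.finite(co))) stop("non-finite coordinates in residue table")
  # deterministic ordering: chain appearance order, then seq_pos
  ord <- order(match(residues$chain, unique(residues$chain)),
               residues$seq_pos)
  residues <- residues[ord, c("chain", "seq_pos", "aa",
                              paste0(rep(c("n", "ca", "c", "cb"),
                                         each = 3),
                                     "_", c("x", "y", "z")),
                              "cb_virtual"), drop = FALSE]
  rownames(residues) <- NULL
  structure(list(model_id = model_id,
                 residues = residues,
                 chain_ids = unique(residues$chain)),
            class = "ComplexStructure")
}

#' @export
print.ComplexStructure <- function(x, ...) {
  cat(sprintf("<ComplexStructure '%s': %d chains, %d residues>\n",
              x$model_id, length(x$chain_ids), nrow(x$residues)))
  invisible(x)
}

n_residues <- function(s) nrow(s$residues)

#' Parse a multimeric model structure from a PDB file
#'
#' Reads the first model, keeps `ATOM` records (plus `HETATM` records whose
#' residue name maps to a standard amino acid, e.g. MSE), prefers altloc
#' 'A'/blank, excludes waters and other solvent/hetero species, and drops
#' residues missing any of N, CA, C with a warning. CB is taken from the
#' file where present and reconstructed virtually otherwise.
#'
#' @param path path to a PDB file
#' @param model_id identifier for the parsed model (default: file stem)
#' @return a [complex_structure()] object
#' @export
parse_structure <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  mapped <- map_residue_name(at$resid)
  keep <- (at$type == "ATOM" & !is.na(mapped)) |
    (at$type == "HETATM" & toupper(at$resid) %in% names(AA_PARENT))
  at <- at[keep, , drop = FALSE]
  mapped <- map_residue_name(at$resid)
  if (nrow(at) == 0L) stop("no usable protein residues in '", path, "'")
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, ins, sep = "|")
  ukey <- unique(key)
  rows <- lapply(ukey, function(k) {
    sel <- which(key == k)
    sub <- at[sel, , drop = FALSE]
    get1 <- function(name) {
      i <- which(sub$elety == name)[1L]
      if (is.na(i)) return(c(NA_real_, NA_real_, NA_real_))
      c(sub$x[i], sub$y[i], sub$z[i])
    }
    n <- get1("N"); ca <- get1("CA"); cc <- get1("C"); cb <- get1("CB")
    data.frame(chain = sub$chain[1L], resno = sub$resno[1L],
               insert = ins[sel[1L]], aa = mapped[sel[1L]],
               n_x = n[1], n_y = n[2], n_z = n[3],
               ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
               c_x = cc[1], c_y = cc[2], c_z = cc[3],
               cb_x = cb[1], cb_y = cb[2], cb_z = cb[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  bad <- is.na(res$n_x) | is.na(res$ca_x) | is.na(res$c_x)
  if (any(bad)) {
    warning(sum(bad), " residue(s) missing backbone atoms dropped")
    res <- res[!bad, , drop = FALSE]
  }
  if (nrow(res) == 0L) stop("no residues with complete backbone in '",
                            path, "'")
  # order within chain by author numbering + insertion code, then renumber
  ord <- order(match(res$chain, unique(res$chain)), res$resno,
               res$insert)
  res <- res[ord, , drop = FALSE]
  res$seq_pos <- stats::ave(seq_len(nrow(res)), res$chain,
                            FUN = seq_along)
  res$resno <- NULL
  res$insert <- NULL
  if (is.null(model_id)) {
    model_id <- sub("\\.[^.]*$", "", basename(path))
  }
  complex_structure(res, model_id = model_id)
}

#' Ideal-geometry virtual CB placement
#'
#' Places a CB-like point from the backbone N, CA, C using the standard
#' fixed linear combination of the CA->N, CA->C frame (tetrahedral
#' geometry: ~1.53 A bond, ~110 degree angles, L-amino-acid chirality).
#' Needed so glycine participates in CB-based distances and dihedrals.
#'
#' @param n,ca,c coordinate matrices (k x 3) or length-3 vectors
#' @return k x 3 matrix of virtual CB coordinates
#' @export
virtual_cb <- function(n, ca, c) {
  if (!is.matrix(n)) n <- matrix(n, nrow = 1L)
  if (!is.matrix(ca)) ca <- matrix(ca, nrow = 1L)
  if (!is.matrix(c)) c <- matrix(c, nrow = 1L)
  b <- ca - n
  cc <- c - ca
  a <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
             b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
             b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Extract a single residue record
#'
#' @param s a `ComplexStructure`
#' @param i global residue index (1-based, chain order then position)
#' @return list with `chain_id`, `seq_pos`, `aa` and an `atoms` list of
#'   3-vectors (N, CA, C, CB)
#' @export
get_residue <- function(s, i) {
  r <- s$residues[i, ]
  list(chain_id = r$chain, seq_pos = r$seq_pos, aa = r$aa,
       atoms = list(N = c(r$n_x, r$n_y, r$n_z),
                    CA = c(r$ca_x, r$ca_y, r$ca_z),
                    C = c(r$c_x, r$c_y, r$c_z),
                    CB = c(r$cb_x, r$cb_y, r$cb_z)),
       cb_virtual = r$cb_virtual)
}

#' Representative atom of a residue
#'
#' CB for all residues except glycine, for which CA is used.
#'
#' @param r a residue record from [get_residue()]
#' @return length-3 coordinate
#' @export
representative_atom <- function(r) {
  if (r$aa == "GLY") {
    ca <- r$atoms$CA
    if (is.null(ca) || anyNA(ca)) stop("glycine residue without CA")
    return(ca)
  }
  cb <- r$atoms$CB
  if (!is.null(cb) && !anyNA(cb)) return(cb)
  a <- r$atoms
  if (anyNA(a$N) || anyNA(a$CA) || anyNA(a$C)) {
    stop("residue has neither CB nor a complete backbone to derive one")
  }
  drop(virtual_cb(a$N, a$CA, a$C))
}

# Vectorised representative coordinates for a whole structure (n x 3).
representative_coords <- function(s) {
  r <- s$residues
  out <- as.matrix(r[, c("cb_x", "cb_y", "cb_z")])
  gly <- r$aa == "GLY"
  out[gly, ] <- as.matrix(r[gly, c("ca_x", "ca_y", "ca_z")])
  dimnames(out) <- NULL
  out
}

#' Write a complex structure as a PDB file
#'
#' Minimal fixed-width ATOM writer (N, CA, C and non-virtual CB per
#' residue) so synthetic structures round-trip through [parse_structure()].
#'
#' @param s a `ComplexStructure`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb_complex <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  res <- s$residues
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    atoms <- list(N = c(r$n_x, r$n_y, r$n_z),
                  CA = c(r$ca_x, r$ca_y, r$ca_z),
                  C = c(r$c_x, r$c_y, r$c_z))
    if (!r$cb_virtual) atoms$CB <- c(r$cb_x, r$cb_y, r$cb_z)
    for (nm in names(atoms)) {
      serial <- serial + 1L
      xyz <- atoms[[nm]]
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, r$aa, substr(r$chain, 1L, 1L), r$seq_pos,
        xyz[1], xyz[2], xyz[3], 1.0, 0.0, substr(nm, 1L, 1L)), con)
    }
    nxt <- if (i < nrow(res)) res$chain[i + 1L] else NA
    if (is.na(nxt) || nxt != r$chain) {
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %3s %1s%4d", serial, r$aa,
                         substr(r$chain, 1L, 1L), r$seq_pos), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

# Apply a rigid-body transform (3x3 rotation + translation) to all atoms.
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  res <- s$residues
  for (at in c("n", "ca", "c", "cb")) {
    cols <- paste0(at, "_", c("x", "y", "z"))
    res[cols] <- sweep(as.matrix(res[cols]) %*% t(rotation), 2L,
                       translation, "+")
  }
  out <- s
  out$residues <- res
  out
}

# Uniform random rotation matrix (axis-angle with bounded angle, degrees).
random_rotation <- function(max_angle_deg) {
  if (max_angle_deg <= 0) return(diag(3))
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}
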