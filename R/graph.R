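# Residue contact graph: nodes are residues, an undirected edge joins any
# pair whose representative atoms (CB; CA for glycine) are within a cutoff
# (default 8 A). Interface residues are nodes with at least one cross-chain
# edge. Neighbour search uses spatial cell binning so large structures do
# not pay the all-pairs cost.

#' Build the residue contact graph of a complex
#'
#' @param s a `ComplexStructure`
#' @param cutoff contact distance in Angstrom (default 8.0; pairs at
#'   exactly the cutoff are included)
#' @return a `ResidueGraph`: `edges` (m x 2 matrix of global residue
#'   indices, i < j), `rep_coords` (n x 3), `cross_chain_mask` (per-edge),
#'   `interface_mask` (per-node), plus node bookkeeping columns
#' @export
build_graph <- function(s, cutoff = 8.0) {
  stopifnot(inherits(s, "ComplexStructure"), cutoff > 0)
  xyz <- representative_coords(s)
  n <- nrow(xyz)
  edges <- cell_list_pairs(xyz, cutoff)
  chain <- s$residues$chain
  cross <- if (nrow(edges)) chain[edges[, 1]] != chain[edges[, 2]] else
    logical(0)
  interface <- rep(FALSE, n)
  if (any(cross)) {
    interface[unique(as.vector(edges[cross, , drop = FALSE]))] <- TRUE
  }
  structure(list(model_id = s$model_id,
                 nodes = seq_len(n),
                 chain = chain,
                 seq_pos = s$residues$seq_pos,
                 edges = edges,
                 rep_coords = xyz,
                 cross_chain_mask = cross,
                 interface_mask = interface,
                 cutoff = cutoff),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat(sprintf(
    "<ResidueGraph '%s': %d nodes, %d edges (%d cross-chain), cutoff %g A>\n",
    x$model_id, length(x$nodes), nrow(x$edges), sum(x$cross_chain_mask),
    x$cutoff))
  invisible(x)
}

# All unordered pairs within `cutoff`, via binning into cubic cells of side
# `cutoff` and scanning the 27-cell neighbourhoods. Returns m x 2 (i < j).
cell_list_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  cell <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  cut2 <- cutoff^2
  for (k in names(buckets)) {
    ii <- buckets[[k]]
    ck <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- buckets[[paste(ck[1] + offs[o, 1], ck[2] + offs[o, 2],
                           ck[3] + offs[o, 3], sep = ",")]]
      if (!is.null(nb)) cand <- c(cand, nb)
    }
    for (i in ii) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
        (xyz[js, 3] - xyz[i, 3])^2
      hit <- js[d2 <= cut2]
      if (length(hit)) {
        out_i <- c(out_i, rep.int(i, length(hit)))
        out_j <- c(out_j, hit)
      }
    }
  }
  if (!length(out_i)) return(matrix(integer(0), 0L, 2L))
  m <- cbind(out_i, out_j)
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Interface residues of a contact graph
#'
#' A residue is an interface residue when it lies within the contact cutoff
#' of any residue from another chain, i.e. when it is incident to at least
#' one cross-chain edge.
#'
#' @param g a `ResidueGraph`
#' @return logical vector over nodes
#' @export
interface_residues <- function(g) {
  stopifnot(inherits(g, "ResidueGraph"))
  if (length(unique(g$chain)) < 2L) {
    warning("single-chain structure: no interface residues possible")
  }
  g$interface_mask
}

#' Export a residue graph as JSON
#'
#' Writes nodes (chain, position), edges (1-based index pairs), the
#' cross-chain edge mask and the interface mask for external inspection.
#'
#' @param g a `ResidueGraph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graph_json <- function(g, path) {
  obj <- list(model_id = g$model_id,
              cutoff = g$cutoff,
              nodes = data.frame(index = g$nodes, chain = g$chain,
                                 seq_pos = g$seq_pos,
                                 interface = g$interface_mask),
              edges = data.frame(
                i = if (nrow(g$edges)) g$edges[, 1] else integer(0),
                j = if (nrow(g$edges)) g$edges[, 2] else integer(0),
                cross_chain = g$cross_chain_mask))
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
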