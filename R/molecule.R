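#' Construct a small-molecule (ligand) object
#'
#' The ligand data model: an ordered atom list with element symbols and
#' Cartesian coordinates, a bond table, detected (or explicitly restricted)
#' rotatable bonds, and a library of conformers sharing the atom order.
#' Conformer 1 is always the input geometry.
#'
#' Rotatable bonds are detected topologically: a bond is rotatable when it
#' is a single bond between two heavy atoms, is not part of a ring (i.e. it
#' is a bridge of the bond graph), and each end atom has at least one other
#' heavy neighbor (so rotating it changes the geometry).
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords n x 3 numeric matrix of coordinates, Angstrom.
#' @param bonds Matrix or data.frame with columns `from`, `to`, `order`
#'   (1-based atom indices). May have zero rows for a single atom.
#' @param conformers Optional list of n x 3 coordinate matrices to use as
#'   the conformer library; the input `coords` is prepended as conformer 1
#'   unless it is already the first entry.
#' @param rotatable Optional integer vector of bond-row indices overriding
#'   the detected rotatable bonds (must be a subset of them). The synthetic
#'   fixture generator uses this to emulate rigidified bonds (conjugation,
#'   amide character) that a bare bond table cannot express.
#' @param name Molecule name carried through SDF output.
#' @return An object of class `ligand_mol` with fields `elements`, `coords`,
#'   `bonds`, `rotatable_bonds`, `conformers`, `is_heavy`, `neighbor_atom`,
#'   `name`.
#' @examples
#' butane <- molecule(rep("C", 4),
#'   cbind(c(0, 1.5, 3, 4.5), 0, 0),
#'   data.frame(from = 1:3, to = 2:4, order = 1))
#' butane$rotatable_bonds  # the central C2-C3 bond
#' @export
molecule <- function(elements, coords, bonds, conformers = NULL,
                     rotatable = NULL, name = "LIG") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements),
            all(is.finite(coords)))
  bonds <- as_bond_table(bonds)
  is_heavy <- !is_hydrogen(elements)
  if (!any(is_heavy)) stop("molecule has no heavy atoms", call. = FALSE)

  detected <- detect_rotatable_bonds(elements, bonds)
  if (!is.null(rotatable)) {
    rotatable <- as.integer(rotatable)
    if (!all(rotatable %in% detected)) {
      stop("'rotatable' must be a subset of the topologically rotatable bonds",
           call. = FALSE)
    }
  } else {
    rotatable <- detected
  }

  confs <- list(coords)
  if (!is.null(conformers)) {
    for (cf in conformers) {
      cf <- as.matrix(cf)
      if (!identical(dim(cf), dim(coords))) {
        stop("conformer atom count differs from molecule", call. = FALSE)
      }
      confs <- c(confs, list(cf))
    }
  }

  mol <- structure(list(
    elements = as.character(elements),
    coords = coords,
    bonds = bonds,
    rotatable_bonds = rotatable,
    conformers = confs,
    is_heavy = is_heavy,
    name = name
  ), class = "ligand_mol")
  mol$neighbor_atom <- neighbor_atom(mol)
  mol
}

as_bond_table <- function(bonds) {
  if (is.null(bonds) || NROW(bonds) == 0) {
    return(data.frame(from = integer(), to = integer(), order = integer()))
  }
  bonds <- as.data.frame(bonds)
  names(bonds)[1:3] <- c("from", "to", "order")
  bonds$from <- as.integer(bonds$from)
  bonds$to <- as.integer(bonds$to)
  bonds$order <- as.integer(bonds$order)
  bonds
}

# Rotatable = acyclic (bridge) single bond between heavy atoms, each end
# bearing >= 1 further heavy neighbor. Returns bond-row indices.
detect_rotatable_bonds <- function(elements, bonds) {
  if (nrow(bonds) == 0) return(integer())
  heavy <- !is_hydrogen(elements)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(elements)) {
    g <- igraph::add_vertices(g, length(elements) - igraph::vcount(g))
  }
  bridge_idx <- as.integer(igraph::bridges(g))
  # heavy-neighbor counts per atom
  adj <- igraph::as_adj_list(g)
  n_heavy_nb <- vapply(adj, function(nb) sum(heavy[as.integer(nb)]), 0L)
  out <- integer()
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$from[i]; b <- bonds$to[i]
    if (bonds$order[i] != 1L) next
    if (!(heavy[a] && heavy[b])) next
    if (!(i %in% bridge_idx)) next
    if (n_heavy_nb[a] < 2L || n_heavy_nb[b] < 2L) next
    out <- c(out, i)
  }
  out
}

#' @export
print.ligand_mol <- function(x, ...) {
  cat(sprintf(
    "ligand_mol '%s': %d atoms (%d heavy), %d bonds, %d rotatable, %d conformer(s)\n",
    x$name, length(x$elements), sum(x$is_heavy), nrow(x$bonds),
    length(x$rotatable_bonds), length(x$conformers)))
  invisible(x)
}

#' Index of the ligand's neighbor atom
#'
#' The neighbor atom is the heavy atom closest to the unweighted geometric
#' center of the ligand's heavy atoms (conformer 1 geometry). It is used as
#' a cheap single-point probe of the scoring grid during the Translate step
#' and as the reference point for the Transform sampler's box constraint.
#' Ties are broken by lowest atom index.
#'
#' @param mol A [molecule()].
#' @return Integer atom index.
#' @export
neighbor_atom <- function(mol) {
  heavy <- which(mol$is_heavy)
  if (length(heavy) == 0) stop("molecule has no heavy atoms", call. = FALSE)
  xyz <- mol$conformers[[1]][heavy, , drop = FALSE]
  ctr <- centroid(xyz)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  heavy[which.min(d2)]  # which.min takes the first (lowest index) on ties
}

heavy_coords <- function(mol, coords = NULL) {
  if (is.null(coords)) coords <- mol$coords
  coords[mol$is_heavy, , drop = FALSE]
}

#' Construct a receptor object
#'
#' A rigid receptor: heavy atoms with a backbone designation (true for the
#' protein main-chain atoms N, CA, C, O of standard residues), residue and
#' chain labels, and the receptor center of mass. The center of mass is the
#' unweighted centroid of the heavy atoms (a declared convention: no mass
#' weighting).
#'
#' @param elements Character vector of element symbols.
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param backbone Logical vector flagging backbone heavy atoms.
#' @param atom_names,resid,resno,chain Optional per-atom PDB-style labels.
#' @return An object of class `receptor`.
#' @export
receptor <- function(elements, coords, backbone,
                     atom_names = NULL, resid = NULL, resno = NULL,
                     chain = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  stopifnot(nrow(coords) == n, length(backbone) == n, all(is.finite(coords)))
  is_heavy <- !is_hydrogen(elements)
  backbone <- as.logical(backbone) & is_heavy
  if (n == 0) stop("receptor has no atoms", call. = FALSE)
  structure(list(
    elements = as.character(elements),
    coords = coords,
    backbone = backbone,
    is_heavy = is_heavy,
    atom_names = atom_names %||% rep(NA_character_, n),
    resid = resid %||% rep("UNK", n),
    resno = resno %||% rep(1L, n),
    chain = chain %||% rep("A", n),
    center_of_mass = centroid(coords[is_heavy, , drop = FALSE])
  ), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("receptor: %d atoms (%d heavy, %d backbone), COM (%.2f, %.2f, %.2f)\n",
              length(x$elements), sum(x$is_heavy), sum(x$backbone),
              x$center_of_mass[1], x$center_of_mass[2], x$center_of_mass[3]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
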