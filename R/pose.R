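#' Construct a ligand pose
#'
#' One placement of a ligand conformer in the receptor frame: the molecule,
#' the conformer index it was built from, the current Cartesian coordinates,
#' the cumulative orientation relative to the library conformer, and any
#' scores computed so far. Rigid moves update `coords` and `orientation`
#' together, so a pose can always be reconstructed as a rigid transform of
#' its library conformer.
#'
#' @param mol A [molecule()].
#' @param coords n x 3 coordinate matrix; defaults to conformer
#'   `conformer`'s geometry.
#' @param conformer Conformer index (1-based).
#' @param orientation 3x3 rotation relating the (centered) library conformer
#'   to the current coordinates.
#' @param grid_score,fa_score,rmsd Optional scores.
#' @param flags Character vector of status flags (e.g. `"translate_failed"`).
#' @param provenance Free-form list (algorithm tag, seed, cycle).
#' @return An object of class `pose`.
#' @export
pose <- function(mol, coords = NULL, conformer = 1L, orientation = diag(3),
                 grid_score = NA_real_, fa_score = NA_real_,
                 rmsd = NA_real_, flags = character(), provenance = list()) {
  if (is.null(coords)) coords <- mol$conformers[[conformer]]
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(mol$elements))
  structure(list(
    mol = mol, coords = coords, conformer = as.integer(conformer),
    orientation = orientation, grid_score = grid_score,
    fa_score = fa_score, rmsd = rmsd, flags = flags,
    provenance = provenance
  ), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf(
    "pose: conformer %d, grid_score %s, fa_score %s, rmsd %s%s\n",
    x$conformer, format(x$grid_score), format(x$fa_score), format(x$rmsd),
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Heavy-atom RMSD of a pose to reference coordinates
#'
#' Convenience wrapper around [ligand_rmsd()] extracting the pose's
#' heavy-atom coordinates.
#'
#' @param p A [pose()].
#' @param native n x 3 heavy-atom reference coordinates (native pose).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(p, native) {
  ligand_rmsd(as.matrix(native), heavy_coords(p$mol, p$coords))
}

# Apply a rigid transform to a pose about its heavy-atom centroid,
# keeping the cumulative orientation in sync.
transform_pose <- function(p, tf) {
  pose_rigid_move(p, tf$rotation, tf$translation)
}

# hot-path variant on raw rotation matrix + translation vector
pose_rigid_move <- function(p, R, t) {
  piv <- colMeans(p$coords[p$mol$is_heavy, , drop = FALSE])
  p$coords <- rigid_move(p$coords, R, t, piv)
  p$orientation <- R %*% p$orientation
  p$grid_score <- NA_real_
  p$fa_score <- NA_real_
  p
}

# Place conformer `k` of the pose's molecule at the pose's current centroid
# with the pose's current cumulative orientation. Deterministic: the new
# conformer inherits the orientation the pose has accumulated, so a swap
# changes internal geometry only.
swap_conformer <- function(p, k) {
  mol <- p$mol
  cur_ctr <- centroid(heavy_coords(mol, p$coords))
  lib <- mol$conformers[[k]]
  lib_ctr <- centroid(heavy_coords(mol, lib))
  centered <- sweep(lib, 2, lib_ctr)
  p$coords <- sweep(centered %*% t(p$orientation), 2, cur_ctr, "+")
  p$conformer <- as.integer(k)
  p$grid_score <- NA_real_
  p$fa_score <- NA_real_
  p
}

# Move a pose's heavy-atom centroid to `target`.
center_pose_at <- function(p, target) {
  ctr <- centroid(heavy_coords(p$mol, p$coords))
  p$coords <- sweep(p$coords, 2, as.numeric(target) - ctr, "+")
  p$grid_score <- NA_real_
  p$fa_score <- NA_real_
  p
}
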