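#' Generate a synthetic ligand of controlled shape and flexibility
#'
#' Builds an all-carbon pseudo-ligand with a known geometry:
#' \describe{
#'   \item{rod}{an extended zig-zag chain (alkane-like backbone), elongated
#'     along one axis;}
#'   \item{bent}{a chain with a ~110 degree elbow at its midpoint;}
#'   \item{globular}{a compact cluster with minimum-spanning-tree bonding.}
#' }
#' Bond lengths are ~1.5 A. The number of rotatable bonds is controlled by
#' restricting the topologically rotatable set (see [molecule()]'s
#' `rotatable` argument): chemically this emulates conjugated or otherwise
#' rigidified bonds that a bare connection table cannot express.
#'
#' @param n_atoms Number of heavy atoms (3-30).
#' @param shape `"rod"`, `"bent"` or `"globular"`.
#' @param n_rotbonds Number of rotatable bonds to retain (0-3); capped at
#'   the topologically available count.
#' @return A [molecule()].
#' @export
make_synthetic_ligand <- function(n_atoms, shape = c("rod", "bent", "globular"),
                                  n_rotbonds = 0) {
  shape <- match.arg(shape)
  stopifnot(n_atoms >= 3, n_atoms <= 30, n_rotbonds >= 0, n_rotbonds <= 3)
  if (shape == "rod") {
    i <- seq_len(n_atoms)
    coords <- cbind(1.45 * (i - 1), 0, 0.4 * (i %% 2))  # bond length ~1.50 A
    bonds <- data.frame(from = 1:(n_atoms - 1), to = 2:n_atoms, order = 1L)
  } else if (shape == "bent") {
    half <- ceiling(n_atoms / 2)
    coords <- matrix(0, n_atoms, 3)
    for (i in seq_len(n_atoms)) {
      if (i <= half) {
        coords[i, ] <- c(1.45 * (i - 1), 0, 0.4 * (i %% 2))
      } else {
        k <- i - half
        # second arm at ~113 degrees in the xy-plane, same bond length
        coords[i, ] <- c(1.45 * (half - 1) + 0.6 * k, 1.32 * k, 0.4 * (i %% 2))
      }
    }
    bonds <- data.frame(from = 1:(n_atoms - 1), to = 2:n_atoms, order = 1L)
  } else {
    # compact cluster: deterministic spherical spiral, scaled for ~1.5 A
    # nearest-neighbor separations, bonded by minimum spanning tree
    i <- seq_len(n_atoms)
    phi <- acos(1 - 2 * (i - 0.5) / n_atoms)
    theta <- pi * (1 + sqrt(5)) * i
    r <- 0.8 * n_atoms^(1 / 3) + 0.7
    coords <- r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    d <- as.matrix(stats::dist(coords))
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst)
    bonds <- data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                        order = 1L)
  }
  mol <- molecule(rep("C", n_atoms), coords, bonds,
                  name = sprintf("%s%02d", toupper(substr(shape, 1, 3)), n_atoms))
  avail <- mol$rotatable_bonds
  keep <- if (n_rotbonds == 0 || length(avail) == 0) {
    integer()
  } else {
    # spread the retained rotatable bonds evenly along the available set
    avail[unique(round(seq(1, length(avail),
                           length.out = min(n_rotbonds, length(avail)))))]
  }
  molecule(mol$elements, mol$coords, mol$bonds, rotatable = keep,
           name = mol$name)
}

# Place `m` points on a circle of radius `rho` in the plane through
# `center` perpendicular to `axis`.
ring_points <- function(center, axis, rho, m, phase = 0) {
  u <- axis / sqrt(sum(axis^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- phase + 2 * pi * (seq_len(m) - 1) / m
  t(vapply(ang, function(th) center + rho * (cos(th) * e1 + sin(th) * e2),
           numeric(3)))
}

# Points on a sphere around `center` (Fibonacci lattice).
sphere_points <- function(center, radius, m) {
  i <- seq_len(m)
  phi <- acos(1 - 2 * (i - 0.5) / m)
  theta <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi)), 2, center, "+")
}

#' Generate a synthetic protein-ligand complex with a known native pose
#'
#' Builds a pseudo-receptor pocket around a synthetic ligand placed in its
#' native pose, so that docking accuracy can be measured exactly. Receptor
#' atoms are laid on shells 3.0-4.5 A from the native ligand atoms — inside
#' the attractive band of the classic grid — and flagged as backbone, so
#' the pocket walls are repulsive at close range. Four pocket archetypes
#' are available:
#' \describe{
#'   \item{rod_channel}{a straight tube around a rod ligand, open at one
#'     end — enterable only in the correct orientation;}
#'   \item{bent_channel}{a tube following a bent ligand;}
#'   \item{imprint}{a shell moulded around the whole ligand with an
#'     entrance cone — the native placement satisfies the Rotate-step
#'     acceptance rule on the default grid;}
#'   \item{open_shelf}{a flat slab under the ligand — a shallow,
#'     orientation-tolerant site.}
#' }
#' The start coordinate is offset from the native centroid (along the
#' pocket opening, <= 5 A) with a small seeded jitter, and the scoring grid
#' is sized so the full translation range keeps the ligand in the grid.
#' Generation is deterministic given `seed`.
#'
#' @param pocket_kind One of `"rod_channel"`, `"bent_channel"`,
#'   `"imprint"`, `"open_shelf"`.
#' @param n_atoms Ligand heavy-atom count (default 8).
#' @param n_rotbonds Retained rotatable bonds, 0-3 (default 0).
#' @param seed Integer seed (default 1).
#' @param max_conformers Conformer-library cap passed to
#'   [conformer_enumerate()] (default 100).
#' @return An object of class `synthetic_complex`: fields `receptor`,
#'   `ligand` (conformer library attached), `native_pose`, `native_heavy`,
#'   `pocket_kind`, `grid`, `cfg` (a [placement_config()] with the start
#'   coordinate set), `seed`.
#' @export
make_synthetic_complex <- function(pocket_kind = c("rod_channel",
                                                   "bent_channel",
                                                   "imprint", "open_shelf"),
                                   n_atoms = 8, n_rotbonds = 0, seed = 1,
                                   max_conformers = 100) {
  pocket_kind <- match.arg(pocket_kind)
  set.seed(seed)
  # imprint uses the bent ligand: a moulded shell can only encode the
  # native orientation if the ligand shape is itself asymmetric (a
  # quasi-spherical cluster fits its own imprint in many orientations)
  shape <- switch(pocket_kind, rod_channel = "rod", bent_channel = "bent",
                  imprint = "bent", open_shelf = "globular")
  lig <- make_synthetic_ligand(n_atoms, shape, n_rotbonds)
  lig <- conformer_enumerate(lig, max_conformers)
  native <- lig$conformers[[1]]
  hmask <- lig$is_heavy
  nh <- native[hmask, , drop = FALSE]
  ctr <- centroid(nh)

  rho <- 3.5   # inner wall radius: middle of the attractive band
  rho2 <- 6.0  # outer wall layer: mimics the solid protein body around a
               # buried site, so the pocket exterior is not one thin shell
               # with its own attractive halo right next to the channel
  if (pocket_kind %in% c("rod_channel", "bent_channel")) {
    walls <- list()
    n <- nrow(nh)
    for (i in seq_len(n)) {
      tangent <- if (i < n) nh[i + 1, ] - nh[i, ] else nh[i, ] - nh[i - 1, ]
      walls[[length(walls) + 1L]] <-
        ring_points(nh[i, ], tangent, rho, 8, phase = 0.3 * i)
      walls[[length(walls) + 1L]] <-
        ring_points(nh[i, ], tangent, rho2, 12, phase = 0.3 * i + 0.26)
    }
    # cap the entry (-axis) end so the channel is open at the far end only
    first_tan <- nh[2, ] - nh[1, ]
    first_tan <- first_tan / sqrt(sum(first_tan^2))
    walls[[length(walls) + 1L]] <-
      ring_points(nh[1, ] - rho * first_tan, first_tan, 1.8, 5)
    walls[[length(walls) + 1L]] <-
      matrix(nh[1, ] - rho * first_tan, 1, 3)
    walls[[length(walls) + 1L]] <-
      ring_points(nh[1, ] - rho2 * first_tan, first_tan, 3.0, 8)
    wall <- do.call(rbind, walls)
    # clearance: near the elbow of a bent channel, rings raised on one arm
    # can intrude into the other arm's space
    wall <- wall[apply(pair_dists(wall, nh), 1, min) >= 3.0, , drop = FALSE]
    last_tan <- nh[n, ] - nh[n - 1, ]
    opening <- last_tan / sqrt(sum(last_tan^2))
  } else if (pocket_kind == "imprint") {
    opening <- c(0, 0, 1)
    cand <- do.call(rbind, lapply(seq_len(nrow(nh)), function(i) {
      rbind(sphere_points(nh[i, ], rho, 26),
            sphere_points(nh[i, ], rho2, 40))
    }))
    # keep points in/outside the attractive band of every ligand atom,
    # outside the entrance cone, and mutually separated
    dmin <- apply(pair_dists(cand, nh), 1, min)
    cand <- cand[dmin >= 3.0, , drop = FALSE]
    rel <- sweep(cand, 2, ctr)
    cosang <- rel %*% opening / sqrt(rowSums(rel^2))
    cand <- cand[cosang < 0.55, , drop = FALSE]  # ~57 degree entrance cone
    wall <- dedupe_points(cand, 1.7)
  } else {  # open_shelf
    opening <- c(0, 0, 1)
    zmin <- min(nh[, 3])
    xs <- seq(min(nh[, 1]) - 4, max(nh[, 1]) + 4, by = 1.8)
    ys <- seq(min(nh[, 2]) - 4, max(nh[, 2]) + 4, by = 1.8)
    wall <- as.matrix(expand.grid(x = xs, y = ys, z = zmin - rho))
  }

  nw <- nrow(wall)
  rec <- receptor(rep("C", nw), wall, backbone = rep(TRUE, nw),
                  atom_names = rep("CA", nw), resid = rep("GLY", nw),
                  resno = seq_len(nw), chain = rep("A", nw))

  # start coordinate: toward the opening, jittered, <= 5 A from the native
  # centroid so the configured translation radius can always reach back
  off <- 4.0 * opening + uniform_in_ball(0.8)
  if (sqrt(sum(off^2)) > 5) off <- off * 5 / sqrt(sum(off^2))
  start <- ctr + off

  extent <- max(stats::dist(nh))
  side <- extent + 2 * 5.0 + 2
  grid <- build_classic_grid(rec, center = ctr, side = side)
  cfg <- placement_config(start_coord = start)

  native_pose <- pose(lig, coords = native, grid_score =
                        score_ligand(grid, nh)$score)
  native_pose$rmsd <- 0
  structure(list(receptor = rec, ligand = lig, native_pose = native_pose,
                 native_heavy = nh, pocket_kind = pocket_kind, grid = grid,
                 cfg = cfg, seed = seed),
            class = "synthetic_complex")
}

#' @export
print.synthetic_complex <- function(x, ...) {
  cat(sprintf(
    "synthetic_complex '%s' (seed %d): %d receptor atoms, ligand %s with %d conformer(s)\n",
    x$pocket_kind, x$seed, length(x$receptor$elements), x$ligand$name,
    length(x$ligand$conformers)))
  invisible(x)
}

#' Write a synthetic complex to PDB/SDF files
#'
#' Materialises the receptor as `<prefix>_receptor.pdb`, the ligand
#' conformer library as `<prefix>_ligand.sdf` (one record per conformer)
#' and the native pose as `<prefix>_native.sdf`. Output is deterministic
#' for a given complex, so identical seeds yield byte-identical files.
#'
#' @param x A [make_synthetic_complex()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_complex <- function(x, prefix) {
  paths <- paste0(prefix, c("_receptor.pdb", "_ligand.sdf", "_native.sdf"))
  write_pdb(x$receptor, paths[1])
  conf_poses <- lapply(seq_along(x$ligand$conformers), function(k) {
    pose(x$ligand, conformer = k)
  })
  write_sdf(conf_poses, paths[2])
  write_sdf(list(x$native_pose), paths[3])
  invisible(paths)
}

# Greedy thinning: keep points at least `min_sep` apart (deterministic).
dedupe_points <- function(pts, min_sep) {
  keep <- integer()
  for (i in seq_len(nrow(pts))) {
    if (length(keep) == 0 ||
        min(sqrt(rowSums(sweep(pts[keep, , drop = FALSE], 2, pts[i, ])^2))) >= min_sep) {
      keep <- c(keep, i)
    }
  }
  pts[keep, , drop = FALSE]
}

#' Enumerate ligand conformers on a torsion grid
#'
#' Generates a conformer library by setting each rotatable bond's torsion
#' to 0, 120 or 240 degrees (all combinations), discarding self-clashing
#' geometries (any internal heavy-atom pair closer than `0.7 * (r_i + r_j)`;
#' 1-2 and 1-3 pairs are exempt since bond lengths and angles are fixed by
#' topology, not torsions), and uniformly subsampling to `max_conformers`
#' (always keeping the input geometry as conformer 1). With no rotatable
#' bonds the library is the single input conformer.
#'
#' @param mol A [molecule()].
#' @param max_conformers Library size cap (default 100).
#' @return The molecule with its `conformers` list replaced.
#' @export
conformer_enumerate <- function(mol, max_conformers = 100) {
  rb <- mol$rotatable_bonds
  if (length(rb) == 0) {
    mol$conformers <- list(mol$conformers[[1]])
    return(mol)
  }
  base <- mol$conformers[[1]]
  sides <- lapply(rb, function(bi) torsion_side(mol, bi))
  angle_sets <- rep(list(c(0, 120, 240)), length(rb))
  combos <- as.matrix(expand.grid(angle_sets))
  lr <- vdw_radius(mol$elements)
  bonded <- matrix(FALSE, nrow(base), nrow(base))
  if (nrow(mol$bonds) > 0) {
    bonded[cbind(mol$bonds$from, mol$bonds$to)] <- TRUE
    bonded[cbind(mol$bonds$to, mol$bonds$from)] <- TRUE
  }
  # exempt 1-2 and 1-3 pairs (fixed by topology) from the clash test
  exempt <- bonded | ((bonded %*% bonded) > 0)
  confs <- list()
  for (ci in seq_len(nrow(combos))) {
    xyz <- base
    for (k in seq_along(rb)) {
      ang <- combos[ci, k]
      if (ang == 0) next
      bi <- rb[k]
      a <- mol$bonds$from[bi]; b <- mol$bonds$to[bi]
      axis <- xyz[b, ] - xyz[a, ]
      R <- rotation_about_axis(axis, ang)
      mov <- sides[[k]]
      xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, xyz[a, ]) %*% t(R),
                          2, xyz[a, ], "+")
    }
    if (!self_clashes(xyz, lr, exempt, mol$is_heavy)) {
      confs[[length(confs) + 1L]] <- xyz
    }
  }
  # the input geometry (all torsions 0) survives its own clash test by
  # construction for sane inputs; make sure it is first regardless
  if (length(confs) == 0 || ligand_rmsd(confs[[1]], base) > 1e-9) {
    confs <- c(list(base), confs)
  }
  if (length(confs) > max_conformers) {
    keep <- c(1L, sort(sample(2:length(confs), max_conformers - 1L)))
    confs <- confs[keep]
  }
  mol$conformers <- confs
  mol$coords <- confs[[1]]
  mol
}

# Atom indices on the distal (`to`) side of bond `bi` when that bond is cut.
torsion_side <- function(mol, bi) {
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(mol$elements)) {
    g <- igraph::add_vertices(g, length(mol$elements) - igraph::vcount(g))
  }
  g2 <- igraph::delete_edges(g, bi)
  comp <- igraph::components(g2)$membership
  which(comp == comp[mol$bonds$to[bi]])
}

self_clashes <- function(xyz, radii, exempt, heavy) {
  idx <- which(heavy)
  if (length(idx) < 2) return(FALSE)
  for (ii in seq_along(idx)[-1]) {
    i <- idx[ii]
    js <- idx[seq_len(ii - 1)]
    js <- js[!exempt[i, js]]
    if (length(js) == 0) next
    d <- sqrt(rowSums(sweep(xyz[js, , drop = FALSE], 2, xyz[i, ])^2))
    lim <- 0.7 * (radii[i] + radii[js])
    if (any(d < lim)) return(TRUE)
  }
  FALSE
}
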