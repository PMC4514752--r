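#' Sentinel for points outside the scoring grid
#'
#' [score_point()] returns this value (`NA_integer_`) for coordinates that
#' fall outside the grid volume. [score_ligand()] converts any out-of-grid
#' heavy atom into a pose score of `+Inf`, which makes the samplers reject
#' such moves without a separate control path.
#' @export
OUT_OF_GRID <- NA_integer_

# Classification radii (Angstrom). A cell is repulsive when its center is
# within REPULSIVE_RADIUS of any backbone heavy atom, else attractive when
# within [REPULSIVE_RADIUS, ATTRACTIVE_RADIUS] of any receptor heavy atom.
REPULSIVE_RADIUS <- 2.25
ATTRACTIVE_RADIUS <- 4.75

#' Build the classic binary attractive/repulsive scoring grid
#'
#' Discretises the binding region into an axis-aligned cube of cells
#' (default 10 A side, 0.25 A spacing, i.e. a cube of 1000 A^3) and
#' classifies each cell by its center point:
#' \itemize{
#'   \item `+1` (repulsive): within 2.25 A of any backbone heavy atom —
#'     placing a ligand atom here implies a backbone clash;
#'   \item `-1` (attractive): between 2.25 and 4.75 A of any receptor heavy
#'     atom — the favorable-contact band;
#'   \item `0` (neutral) otherwise.
#' }
#' Where the two shells overlap, repulsive takes precedence (clash safety
#' first). The repulsive region is the solid sphere r <= 2.25 A.
#'
#' The grid must be large enough that the ligand stays inside it over the
#' sampler's full translation range: when `ligand` is supplied and the
#' requested side is smaller than ligand extent + 2*translate_radius + 2 A,
#' the builder warns and auto-expands to that size.
#'
#' @param rec A [receptor()].
#' @param center Numeric 3-vector: grid center, Angstrom.
#' @param side Cube side length, Angstrom (default 10).
#' @param spacing Cell edge, Angstrom (default 0.25).
#' @param ligand Optional [molecule()] used for the sizing check.
#' @param translate_radius Sampler translation radius used in the sizing
#'   check, Angstrom (default 5).
#' @param repulsive_radius,attractive_radius Shell radii, Angstrom
#'   (defaults 2.25 and 4.75, the classic protocol constants).
#' @return An object of class `scoring_grid` with fields `origin` (minimum
#'   corner), `spacing`, `dims`, `values` (integer 3-D array in
#'   \{-1, 0, +1\}).
#' @export
build_classic_grid <- function(rec, center, side = 10, spacing = 0.25,
                               ligand = NULL, translate_radius = 5,
                               repulsive_radius = REPULSIVE_RADIUS,
                               attractive_radius = ATTRACTIVE_RADIUS) {
  stopifnot(inherits(rec, "receptor"), length(center) == 3,
            side > 0, spacing > 0)
  if (spacing > side) stop("spacing exceeds grid side", call. = FALSE)
  if (!is.null(ligand)) {
    hx <- heavy_coords(ligand, ligand$conformers[[1]])
    extent <- if (nrow(hx) > 1) max(stats::dist(hx)) else 0
    need <- extent + 2 * translate_radius + 2
    if (side < need) {
      warning(sprintf(
        "grid side %.1f A too small for ligand extent %.1f A + %.1f A translations; expanding to %.1f A",
        side, extent, translate_radius, need))
      side <- need
    }
  }
  dims <- rep(max(1L, as.integer(round(side / spacing))), 3)
  origin <- as.numeric(center) - dims * spacing / 2
  if (prod(dims) == 0) stop("grid has zero cells", call. = FALSE)

  axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 0.5) * spacing)
  rep_arr <- array(FALSE, dims)
  attr_arr <- array(FALSE, dims)
  hv <- which(rec$is_heavy)
  r_rep2 <- repulsive_radius^2
  r_attr2 <- attractive_radius^2
  for (a in hv) {
    p <- rec$coords[a, ]
    # local window of cells possibly within the attractive radius
    rng <- lapply(1:3, function(k) {
      which(abs(axes[[k]] - p[k]) <= attractive_radius)
    })
    if (any(lengths(rng) == 0)) next
    dx2 <- (axes[[1]][rng[[1]]] - p[1])^2
    dy2 <- (axes[[2]][rng[[2]]] - p[2])^2
    dz2 <- (axes[[3]][rng[[3]]] - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    attr_arr[rng[[1]], rng[[2]], rng[[3]]] <-
      attr_arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] |
      (d2 >= r_rep2 & d2 <= r_attr2)
    if (rec$backbone[a]) {
      rep_arr[rng[[1]], rng[[2]], rng[[3]]] <-
        rep_arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] | (d2 <= r_rep2)
    }
  }
  values <- array(0L, dims)
  values[attr_arr] <- -1L
  values[rep_arr] <- 1L  # repulsive precedence
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values),
            class = "scoring_grid")
}

#' @export
print.scoring_grid <- function(x, ...) {
  tab <- table(factor(x$values, levels = c(-1, 0, 1)))
  cat(sprintf(
    "scoring_grid: %d x %d x %d cells, %.2f A spacing\n  attractive %d, neutral %d, repulsive %d\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Score points against a grid
#'
#' Returns the value of the cell containing each coordinate. Cell lookup is
#' `floor((coord - origin) / spacing)`: a point exactly on a cell boundary
#' belongs to the higher-index cell. Cell values are categorical, so no
#' interpolation is performed. Out-of-bounds points return [OUT_OF_GRID].
#'
#' @param grid A [build_classic_grid()] result.
#' @param coords A 3-vector or n x 3 matrix.
#' @return Integer vector of cell values (`NA` = out of grid).
#' @export
score_point <- function(grid, coords) {
  coords <- if (is.null(dim(coords))) matrix(coords, ncol = 3) else as.matrix(coords)
  grid_lookup(grid, coords)
}

# hot-path lookup: integer cell values for an n x 3 matrix, NA outside
grid_lookup <- function(grid, hx) {
  sp <- grid$spacing; o <- grid$origin; dm <- grid$dims
  i1 <- floor((hx[, 1] - o[1]) / sp) + 1
  i2 <- floor((hx[, 2] - o[2]) / sp) + 1
  i3 <- floor((hx[, 3] - o[3]) / sp) + 1
  ok <- i1 >= 1 & i1 <= dm[1] & i2 >= 1 & i2 <= dm[2] & i3 >= 1 & i3 <= dm[3]
  out <- rep(NA_integer_, nrow(hx))
  if (all(ok)) {
    out <- grid$values[cbind(i1, i2, i3)]
  } else if (any(ok)) {
    out[ok] <- grid$values[cbind(i1[ok], i2[ok], i3[ok])]
  }
  out
}

#' Grid score of a ligand placement
#'
#' Sum of [score_point()] over the ligand's heavy atoms. If any heavy atom
#' lies outside the grid the total is `+Inf`, implementing the rule that a
#' move placing atoms outside the grid must be rejected.
#'
#' @param grid A scoring grid.
#' @param x A [pose()], or an n x 3 heavy-atom coordinate matrix.
#' @param mol Required when `x` is a full-molecule coordinate matrix with
#'   hydrogens: the [molecule()] providing the heavy-atom mask.
#' @return List with `score` (numeric, possibly `Inf`) and `per_atom`
#'   (integer vector over heavy atoms, `NA` = out of grid).
#' @export
score_ligand <- function(grid, x, mol = NULL) {
  hx <- if (inherits(x, "pose")) heavy_coords(x$mol, x$coords)
        else if (!is.null(mol)) heavy_coords(mol, as.matrix(x))
        else as.matrix(x)
  per <- score_point(grid, hx)
  score <- if (anyNA(per)) Inf else as.numeric(sum(per))
  list(score = score, per_atom = per)
}

#' Clash-free orientation acceptance test (Rotate-step rule)
#'
#' The Rotate step of the legacy placement protocol admits an orientation
#' into its diversity set only when no heavy atom sits in a repulsive cell
#' and at least 85% of the heavy atoms sit in attractive cells. Any atom
#' outside the grid rejects the orientation outright (moves that leave the
#' grid are never allowed).
#'
#' @param grid A scoring grid.
#' @param x A [pose()] or heavy-atom coordinate matrix.
#' @param mol Optional [molecule()] mask (see [score_ligand()]).
#' @param min_attractive_frac Attractive quota (default 0.85).
#' @return List with `accept` (logical), `frac_attractive`,
#'   `frac_repulsive`, `n_out_of_grid`.
#' @export
check_rotate_acceptance <- function(grid, x, mol = NULL,
                                    min_attractive_frac = 0.85) {
  per <- score_ligand(grid, x, mol)$per_atom
  n <- length(per)
  n_rep <- sum(per == 1L, na.rm = TRUE)
  n_attr <- sum(per == -1L, na.rm = TRUE)
  list(accept = !anyNA(per) && n_rep == 0 && n_attr >= min_attractive_frac * n,
       frac_attractive = n_attr / n,
       frac_repulsive = n_rep / n,
       n_out_of_grid = sum(is.na(per)))
}

#' Fingerprint of a receptor's heavy-atom coordinates
#'
#' Deterministic checksum (Horner scheme over the coordinates rounded to
#' 1e-3 A, modulo 2^31 - 1) used by the grid manager to detect that a grid
#' has gone stale with respect to the receptor it was built from.
#'
#' @param rec A [receptor()].
#' @return Integer-valued scalar.
#' @export
receptor_fingerprint <- function(rec) {
  v <- as.numeric(t(rec$coords[rec$is_heavy, , drop = FALSE]))
  v <- round(v * 1000) %% 1048573
  h <- 0
  m <- 2^31 - 1
  for (x in v) h <- (h * 31 + x) %% m
  h
}

#' Create a grid manager
#'
#' Owns a named collection of scoring grids with weights and the
#' fingerprint of the receptor they were built from. The manager's ligand
#' score is the weighted sum of the member grids' scores; it refuses to
#' score against a receptor whose heavy-atom coordinates differ from build
#' time. In this package the collection holds the single classic binary
#' grid, but the container is deliberately pluggable.
#'
#' @param rec The [receptor()] the grids were built from.
#' @param grids Named list of scoring grids.
#' @param weights Numeric weights, one per grid (default all 1).
#' @return An object of class `grid_manager`.
#' @export
grid_manager <- function(rec, grids, weights = NULL) {
  stopifnot(is.list(grids), length(grids) >= 1)
  if (is.null(names(grids)) || any(names(grids) == "")) {
    stop("grids must be a named list", call. = FALSE)
  }
  weights <- weights %||% rep(1, length(grids))
  stopifnot(length(weights) == length(grids))
  structure(list(grids = grids, weights = weights,
                 fingerprint = receptor_fingerprint(rec)),
            class = "grid_manager")
}

#' Score a ligand placement through a grid manager
#'
#' @param mgr A [grid_manager()].
#' @param rec The receptor being docked against; its fingerprint must match
#'   the manager's build-time fingerprint.
#' @param x A [pose()] or heavy-atom coordinate matrix.
#' @param mol Optional [molecule()] mask (see [score_ligand()]).
#' @return Weighted total score (numeric scalar, possibly `Inf`).
#' @export
score_manager <- function(mgr, rec, x, mol = NULL) {
  if (receptor_fingerprint(rec) != mgr$fingerprint) {
    stop("receptor has changed since the grids were built; rebuild the grid manager",
         call. = FALSE)
  }
  sum(vapply(seq_along(mgr$grids), function(i) {
    mgr$weights[i] * score_ligand(mgr$grids[[i]], x, mol)$score
  }, 0))
}

#' Serialize a scoring grid to a text container
#'
#' One JSON header line (origin, spacing, dims, optional receptor
#' fingerprint) followed by the cell values in column-major order.
#'
#' @param grid A scoring grid.
#' @param path Output path.
#' @param fingerprint Optional receptor fingerprint to embed.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, fingerprint = NULL) {
  hdr <- jsonlite::toJSON(list(origin = grid$origin, spacing = grid$spacing,
                               dims = grid$dims, fingerprint = fingerprint),
                          auto_unbox = FALSE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(paste(as.integer(grid$values), collapse = " "), con)
  invisible(path)
}

#' Read a scoring grid written by [write_grid()]
#'
#' @param path Path to a grid container file.
#' @return A `scoring_grid`; any embedded fingerprint is attached as
#'   attribute `"fingerprint"`.
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  vals <- as.integer(strsplit(lines[2], " ", fixed = TRUE)[[1]])
  dims <- as.integer(hdr$dims)
  stopifnot(length(vals) == prod(dims))
  g <- structure(list(origin = as.numeric(hdr$origin),
                      spacing = as.numeric(hdr$spacing),
                      dims = dims,
                      values = array(vals, dims)),
                 class = "scoring_grid")
  if (!is.null(hdr$fingerprint)) attr(g, "fingerprint") <- hdr$fingerprint
  g
}
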