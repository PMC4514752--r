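#' Parameters of the surrogate full-atom score
#'
#' The refinement stage scores poses with a deliberately simple soft-sphere
#' contact potential over ligand-heavy-atom / receptor-heavy-atom pairs:
#' a quadratic penalty for van der Waals overlap plus a triangular
#' attraction well centered at the contact distance. For a pair with radii
#' `r_i`, `r_j` at distance `d`:
#' \deqn{w_{rep} \max(0, (r_i + r_j - tol) - d)^2
#'       - w_{atr} \max(0, 1 - |d - (r_i + r_j)| / width)}
#' The score is zero for a fully separated ligand, continuous in the
#' coordinates, and has cheap numerical gradients — the properties the
#' rigid-body minimiser relies on. The receptor is rigid throughout.
#'
#' @param clash_tolerance Overlap allowed before the repulsive term switches
#'   on, Angstrom (default 0.6).
#' @param attr_well_width Half-width of the triangular contact well,
#'   Angstrom (default 1.5).
#' @param w_rep,w_atr Term weights (defaults 1.0 and 0.25).
#' @return An object of class `fa_params`.
#' @export
fa_params <- function(clash_tolerance = 0.6, attr_well_width = 1.5,
                      w_rep = 1.0, w_atr = 0.25) {
  stopifnot(clash_tolerance > 0, attr_well_width > 0, w_rep > 0, w_atr > 0)
  structure(list(clash_tolerance = clash_tolerance,
                 attr_well_width = attr_well_width,
                 w_rep = w_rep, w_atr = w_atr),
            class = "fa_params")
}

#' Refinement schedule configuration
#'
#' @param method `"min"` (conformer re-selection + one rigid minimisation)
#'   or `"mcm"` (six alternating minimise/perturb steps, best kept, final
#'   minimisation).
#' @param mcm_steps Number of alternating steps in the MCM schedule (even;
#'   default 6).
#' @param perturb_trans,perturb_angle Magnitude of the small random
#'   perturbations on even steps (defaults 0.1 A, 20 degrees).
#' @param max_iter Pattern-search iteration cap (default 60).
#' @param init_trans_step,init_angle_step Initial pattern-search step sizes
#'   (defaults 0.25 A, 5 degrees).
#' @param tol_trans Convergence threshold on the translation step size,
#'   Angstrom (default 0.01).
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(method = c("min", "mcm"), mcm_steps = 6L,
                              perturb_trans = 0.1, perturb_angle = 20,
                              max_iter = 60L, init_trans_step = 0.25,
                              init_angle_step = 5, tol_trans = 0.01) {
  method <- match.arg(method)
  stopifnot(mcm_steps %% 2 == 0, mcm_steps > 0)
  structure(list(method = method, mcm_steps = as.integer(mcm_steps),
                 perturb_trans = perturb_trans, perturb_angle = perturb_angle,
                 max_iter = as.integer(max_iter),
                 init_trans_step = init_trans_step,
                 init_angle_step = init_angle_step, tol_trans = tol_trans),
            class = "refinement_config")
}

# Receptor heavy atoms with radii, prefiltered to a bounding box around
# `coords` expanded by `margin` -- keeps pair loops near-linear in the
# number of actual contacts.
receptor_context <- function(rec, coords = NULL, margin = 8) {
  hv <- which(rec$is_heavy)
  xyz <- rec$coords[hv, , drop = FALSE]
  if (!is.null(coords)) {
    lo <- apply(coords, 2, min) - margin
    hi <- apply(coords, 2, max) + margin
    keep <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
            xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
            xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
    xyz <- xyz[keep, , drop = FALSE]
    hv <- hv[keep]
  }
  list(xyz = xyz, radii = vdw_radius(rec$elements[hv]))
}

#' Count steric clashes between a ligand placement and the receptor
#'
#' A ligand-heavy-atom / receptor-heavy-atom pair clashes when its distance
#' is below `r_i + r_j - clash_tolerance`. Receptor atoms are prefiltered
#' to a bounding box around the ligand so the cost is near-linear in the
#' number of potential contacts.
#'
#' @param x A [pose()] or heavy-atom coordinate matrix.
#' @param rec A [receptor()].
#' @param params [fa_params()].
#' @param mol Optional [molecule()] mask when `x` is a full coordinate
#'   matrix.
#' @return Integer clash count.
#' @export
count_clashes <- function(x, rec, params = fa_params(), mol = NULL) {
  if (inherits(x, "pose")) {
    hx <- heavy_coords(x$mol, x$coords)
    lr <- vdw_radius(x$mol$elements[x$mol$is_heavy])
  } else if (!is.null(mol)) {
    hx <- heavy_coords(mol, as.matrix(x))
    lr <- vdw_radius(mol$elements[mol$is_heavy])
  } else {
    hx <- as.matrix(x)
    lr <- rep(VDW_RADII[["C"]], nrow(hx))
  }
  ctx <- receptor_context(rec, hx)
  if (nrow(ctx$xyz) == 0) return(0L)
  d <- pair_dists(hx, ctx$xyz)
  lim <- outer(lr, ctx$radii, "+") - params$clash_tolerance
  sum(d < lim)
}

# n x m distance matrix between two coordinate sets
pair_dists <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Surrogate full-atom score of a pose against a rigid receptor
#'
#' See [fa_params()] for the functional form. Zero for an isolated ligand;
#' a single pair exactly at contact distance scores `-w_atr`.
#'
#' @inheritParams count_clashes
#' @return Numeric score (finite).
#' @export
fa_score <- function(x, rec, params = fa_params(), mol = NULL) {
  if (inherits(x, "pose")) {
    hx <- heavy_coords(x$mol, x$coords)
    lr <- vdw_radius(x$mol$elements[x$mol$is_heavy])
  } else if (!is.null(mol)) {
    hx <- heavy_coords(mol, as.matrix(x))
    lr <- vdw_radius(mol$elements[mol$is_heavy])
  } else {
    hx <- as.matrix(x)
    lr <- rep(VDW_RADII[["C"]], nrow(hx))
  }
  ctx <- receptor_context(rec, hx)
  fa_score_ctx(hx, lr, ctx, params)
}

# Inner scorer against a prebuilt receptor context (hot path for the
# minimiser: no prefiltering, no S3 dispatch).
fa_score_ctx <- function(hx, lr, ctx, params) {
  if (nrow(ctx$xyz) == 0) return(0)
  d <- pair_dists(hx, ctx$xyz)
  contact <- outer(lr, ctx$radii, "+")
  overlap <- (contact - params$clash_tolerance) - d
  rep_term <- sum(pmax(0, overlap)^2)
  tri <- pmax(0, 1 - abs(d - contact) / params$attr_well_width)
  params$w_rep * rep_term - params$w_atr * sum(tri)
}

#' Rigid-body local minimisation of the surrogate score
#'
#' Derivative-free pattern search over the six rigid degrees of freedom
#' (three translations, three rotations about the heavy-atom centroid).
#' Each iteration polls +/- moves along each axis at the current step
#' sizes, takes the best improving move, and halves the steps when no move
#' improves. Guaranteed non-increasing score; terminates when the
#' translation step falls below `tol_trans` or at `max_iter` iterations.
#'
#' @param p A [pose()].
#' @param rec A [receptor()].
#' @param params [fa_params()].
#' @param cfg [refinement_config()].
#' @return The minimised pose with `fa_score` set.
#' @export
rigid_minimize <- function(p, rec, params = fa_params(),
                           cfg = refinement_config()) {
  mol <- p$mol
  hmask <- mol$is_heavy
  lr <- vdw_radius(mol$elements[hmask])
  # context margin covers the whole search excursion
  ctx <- receptor_context(rec, p$coords[hmask, , drop = FALSE], margin = 10)
  contact <- outer(lr, ctx$radii, "+")
  lim <- contact - params$clash_tolerance
  width <- params$attr_well_width
  scorer <- if (nrow(ctx$xyz) == 0) function(hx) 0 else function(hx) {
    d <- pair_dists(hx, ctx$xyz)
    params$w_rep * sum(pmax(0, lim - d)^2) -
      params$w_atr * sum(pmax(0, 1 - abs(d - contact) / width))
  }
  coords <- p$coords
  ori <- p$orientation
  cur <- scorer(coords[hmask, , drop = FALSE])
  ts <- cfg$init_trans_step
  as <- cfg$init_angle_step
  axes <- diag(3)
  for (iter in seq_len(cfg$max_iter)) {
    improved <- FALSE
    piv <- colMeans(coords[hmask, , drop = FALSE])
    best_coords <- NULL; best_ori <- NULL; best_s <- cur
    for (k in 1:3) {
      for (sgn in c(-1, 1)) {
        # translation poll
        cand <- row_shift(coords, sgn * ts * axes[k, ])
        s <- scorer(cand[hmask, , drop = FALSE])
        if (s < best_s) { best_s <- s; best_coords <- cand; best_ori <- ori }
        # rotation poll
        R <- rotation_about_axis(axes[k, ], sgn * as)
        cand <- rigid_move(coords, R, c(0, 0, 0), piv)
        s <- scorer(cand[hmask, , drop = FALSE])
        if (s < best_s) { best_s <- s; best_coords <- cand; best_ori <- R %*% ori }
      }
    }
    if (best_s < cur - 1e-12) {
      coords <- best_coords; ori <- best_ori; cur <- best_s
      improved <- TRUE
    }
    if (!improved) {
      ts <- ts / 2
      as <- as / 2
      if (ts < cfg$tol_trans) break
    }
  }
  p$coords <- coords
  p$orientation <- ori
  p$fa_score <- cur
  p$grid_score <- NA_real_
  p
}

# Re-select the library conformer minimising fa_score at the pose's
# current placement (centroid + cumulative orientation); stands in for the
# packing cycle's ligand-conformer choice. Ties -> lowest index.
select_best_conformer <- function(p, rec, params) {
  mol <- p$mol
  if (length(mol$conformers) == 1) {
    p$fa_score <- fa_score(p, rec, params)
    return(p)
  }
  best <- NULL; best_s <- Inf
  for (k in seq_along(mol$conformers)) {
    cand <- swap_conformer(p, k)
    s <- fa_score(cand, rec, params)
    if (s < best_s) { best_s <- s; best <- cand }
  }
  best$fa_score <- best_s
  best
}

#' MIN refinement: conformer re-selection plus one rigid minimisation
#'
#' Selects the library conformer with the lowest surrogate score at the
#' current placement, then runs [rigid_minimize()]. For a single-conformer
#' ligand this is exactly one rigid minimisation. Never increases the
#' score.
#'
#' @inheritParams rigid_minimize
#' @return Refined pose.
#' @export
refine_min <- function(p, rec, params = fa_params(),
                       cfg = refinement_config("min")) {
  rigid_minimize(select_best_conformer(p, rec, params), rec, params, cfg)
}

#' MCM refinement: alternating minimisation and perturbation, best kept
#'
#' Six steps (configurable): odd steps perform conformer re-selection
#' followed by rigid minimisation; even steps apply a small random rigid
#' perturbation (default up to 0.1 A and 20 degrees). The pose after each
#' step is recorded, the best-scoring of the recorded poses is kept, and a
#' final rigid minimisation is applied to it. Uses the global RNG; call
#' [set.seed()] for reproducibility.
#'
#' @inheritParams rigid_minimize
#' @return Refined pose.
#' @export
refine_mcm <- function(p, rec, params = fa_params(),
                       cfg = refinement_config("mcm")) {
  cur <- p
  best <- NULL; best_s <- Inf
  for (step in seq_len(cfg$mcm_steps)) {
    if (step %% 2 == 1) {
      cur <- rigid_minimize(select_best_conformer(cur, rec, params),
                            rec, params, cfg)
    } else {
      cur <- transform_pose(
        cur, random_small_perturbation(cfg$perturb_trans, cfg$perturb_angle))
      cur$fa_score <- fa_score(cur, rec, params)
    }
    if (cur$fa_score < best_s) { best_s <- cur$fa_score; best <- cur }
  }
  rigid_minimize(best, rec, params, cfg)
}

#' Refine a pose with the configured schedule
#'
#' Dispatches to [refine_min()] or [refine_mcm()] according to
#' `cfg$method`.
#'
#' @inheritParams rigid_minimize
#' @return Refined pose.
#' @export
refine_pose <- function(p, rec, params = fa_params(),
                        cfg = refinement_config()) {
  switch(cfg$method,
         min = refine_min(p, rec, params, cfg),
         mcm = refine_mcm(p, rec, params, cfg))
}
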