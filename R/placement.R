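#' Configuration for the initial-placement algorithms
#'
#' Bundles every tunable of both placement protocols. The defaults encode
#' the published protocol constants: up to 50 random translations within
#' 5.0 A of the start, up to 500 random rotations accumulating a diversity
#' set of size `max(5, 5 * n_rotatable_bonds)` with a pairwise RMSD floor of
#' `0.65 * sqrt(n_heavy_atoms)`, and 500 Metropolis cycles for the
#' Transform sampler. Per-cycle move magnitudes, the conformer-swap
#' probability and the Monte Carlo temperature are not fixed by the
#' protocol description and are exposed here (see the package vignette for
#' how the defaults were chosen).
#'
#' @param start_coord Numeric 3-vector: starting Cartesian coordinate for
#'   the ligand centroid, receptor frame, Angstrom.
#' @param translate_radius Radius of the Translate step's sampling ball,
#'   Angstrom (default 5.0).
#' @param translate_attempts Maximum Translate proposals (default 50).
#' @param rotate_attempts Maximum Rotate proposals (default 500).
#' @param diversity_base Minimum diversity-set size (default 5).
#' @param diversity_coeff_per_rotbond Set-size multiplier per rotatable
#'   bond (default 5).
#' @param rmsd_diversity_coeff Pairwise RMSD floor coefficient (default
#'   0.65; the floor is `coeff * sqrt(n_heavy)` Angstrom).
#' @param transform_cycles Metropolis cycles for the Transform sampler
#'   (default 500).
#' @param mc_temperature Metropolis temperature on the grid-score scale
#'   (default 1.0).
#' @param per_move_max_trans,per_move_max_angle Per-cycle rigid move caps
#'   (defaults 0.5 A, 30 degrees).
#' @param conformer_swap_prob Probability that a cycle proposes a conformer
#'   swap instead of a rigid move, when a conformer library is present
#'   (default 0.1).
#' @param box_radius Maximum allowed distance of the neighbor atom from
#'   `start_coord` during Transform sampling (default = `translate_radius`).
#' @param slide_step Slide-Together step size, Angstrom (default 0.1).
#' @return An object of class `placement_config`.
#' @export
placement_config <- function(start_coord = c(0, 0, 0),
                             translate_radius = 5.0,
                             translate_attempts = 50L,
                             rotate_attempts = 500L,
                             diversity_base = 5L,
                             diversity_coeff_per_rotbond = 5L,
                             rmsd_diversity_coeff = 0.65,
                             transform_cycles = 500L,
                             mc_temperature = 1.0,
                             per_move_max_trans = 0.5,
                             per_move_max_angle = 30,
                             conformer_swap_prob = 0.1,
                             box_radius = NULL,
                             slide_step = 0.1) {
  stopifnot(length(start_coord) == 3, translate_radius >= 0,
            translate_attempts >= 1, rotate_attempts >= 1,
            diversity_base >= 1, diversity_coeff_per_rotbond >= 0,
            rmsd_diversity_coeff > 0, transform_cycles >= 1,
            mc_temperature > 0, per_move_max_trans >= 0,
            per_move_max_angle >= 0, conformer_swap_prob >= 0,
            conformer_swap_prob <= 1, slide_step > 0)
  structure(list(
    start_coord = as.numeric(start_coord),
    translate_radius = translate_radius,
    translate_attempts = as.integer(translate_attempts),
    rotate_attempts = as.integer(rotate_attempts),
    diversity_base = as.integer(diversity_base),
    diversity_coeff_per_rotbond = as.integer(diversity_coeff_per_rotbond),
    rmsd_diversity_coeff = rmsd_diversity_coeff,
    transform_cycles = as.integer(transform_cycles),
    mc_temperature = mc_temperature,
    per_move_max_trans = per_move_max_trans,
    per_move_max_angle = per_move_max_angle,
    conformer_swap_prob = conformer_swap_prob,
    box_radius = box_radius %||% translate_radius,
    slide_step = slide_step
  ), class = "placement_config")
}

#' Create a sampled-state RMSD log
#'
#' A tiny mutable collector used for sampling-enrichment analysis: the
#' placement algorithms append the RMSD of every state they visit to the
#' supplied native heavy-atom coordinates.
#'
#' @param native n x 3 heavy-atom coordinates of the native pose.
#' @return An environment with fields `native` and `rmsd`.
#' @export
make_state_log <- function(native) {
  e <- new.env(parent = emptyenv())
  e$native <- as.matrix(native)
  e$rmsd <- numeric()
  e
}

log_state <- function(log, heavy_xyz) {
  log$rmsd[length(log$rmsd) + 1L] <- ligand_rmsd(log$native, heavy_xyz)
  invisible(log)
}

uniform_in_ball <- function(radius) {
  if (radius <= 0) return(c(0, 0, 0))
  d <- stats::rnorm(3)
  d / sqrt(sum(d^2)) * radius * stats::runif(1)^(1 / 3)
}

#' Translate step of the legacy placement protocol
#'
#' Proposes up to `translate_attempts` uniform random offsets within
#' `translate_radius` of the starting position, applied to the whole
#' ligand. After each proposal only the neighbor atom is scored on the
#' grid; the first proposal whose cell is attractive or neutral (score -1
#' or 0) is accepted and the step terminates. If every proposal fails, the
#' last proposal is returned with the `"translate_failed"` flag so that
#' batch model generation can continue.
#'
#' @param p Starting [pose()] (ligand centered at the start coordinate).
#' @param grid Scoring grid.
#' @param cfg [placement_config()].
#' @param state_log Optional [make_state_log()] recording each proposal's
#'   RMSD to the native pose.
#' @return A pose; `provenance$translate_attempts_used` records the count.
#' @export
translate_step <- function(p, grid, cfg, state_log = NULL) {
  base <- p$coords
  nb <- p$mol$neighbor_atom
  hmask <- p$mol$is_heavy
  last <- p
  for (i in seq_len(cfg$translate_attempts)) {
    off <- uniform_in_ball(cfg$translate_radius)
    cand <- p
    cand$coords <- sweep(base, 2, off, "+")
    cand$grid_score <- NA_real_
    if (!is.null(state_log)) {
      log_state(state_log, cand$coords[hmask, , drop = FALSE])
    }
    s <- score_point(grid, cand$coords[nb, ])
    if (!is.na(s) && s <= 0L) {
      cand$provenance$translate_attempts_used <- i
      return(cand)
    }
    last <- cand
  }
  last$flags <- union(last$flags, "translate_failed")
  last$provenance$translate_attempts_used <- cfg$translate_attempts
  last
}

#' Rotate step of the legacy placement protocol
#'
#' Accumulates a set of diverse non-clashing orientations and returns one
#' of them at random. Up to `rotate_attempts` uniform random reorientations
#' about the heavy-atom centroid are proposed; a proposal joins the set
#' when [check_rotate_acceptance()] passes (no heavy atom repulsive, >= 85%
#' attractive) and its fixed-frame RMSD to every member already in the set
#' exceeds `rmsd_diversity_coeff * sqrt(n_heavy)`. Proposing stops when the
#' attempt budget is spent or the set reaches
#' `max(diversity_base, diversity_coeff_per_rotbond * n_rotatable)`.
#' An empty set yields the input pose flagged `"rotate_failed"`.
#'
#' @param p Pose from [translate_step()].
#' @param grid Scoring grid.
#' @param cfg [placement_config()].
#' @param keep_set Return the full diversity set in
#'   `provenance$rotate_set` (default FALSE).
#' @param state_log Optional state log created by [make_state_log()]:
#'   every proposed orientation's RMSD to the log's native coordinates is
#'   appended, for sampling-enrichment analysis.
#' @return A pose drawn uniformly from the set.
#' @export
rotate_step <- function(p, grid, cfg, keep_set = FALSE, state_log = NULL) {
  mol <- p$mol
  hmask <- mol$is_heavy
  n_heavy <- sum(hmask)
  target <- max(cfg$diversity_base,
                cfg$diversity_coeff_per_rotbond * length(mol$rotatable_bonds))
  rmsd_floor <- cfg$rmsd_diversity_coeff * sqrt(n_heavy)
  piv <- centroid(p$coords[hmask, , drop = FALSE])

  set_coords <- list()   # full-molecule coords of accepted members
  set_heavy <- list()
  set_ori <- list()
  for (i in seq_len(cfg$rotate_attempts)) {
    R <- rand_rotation_matrix()
    cand <- rigid_move(p$coords, R, c(0, 0, 0), piv)
    ch <- cand[hmask, , drop = FALSE]
    if (!is.null(state_log)) log_state(state_log, ch)
    per <- grid_lookup(grid, ch)
    n_attr <- sum(per == -1L, na.rm = TRUE)
    if (anyNA(per) || any(per == 1L) || n_attr < 0.85 * n_heavy) next
    diverse <- all(vapply(set_heavy, function(m) ligand_rmsd(m, ch) > rmsd_floor,
                          TRUE))
    if (!diverse) next
    set_coords[[length(set_coords) + 1L]] <- cand
    set_heavy[[length(set_heavy) + 1L]] <- ch
    set_ori[[length(set_ori) + 1L]] <- R %*% p$orientation
    if (length(set_coords) >= target) break
  }
  if (length(set_coords) == 0) {
    p$flags <- union(p$flags, "rotate_failed")
    p$provenance$rotate_set_size <- 0L
    return(p)
  }
  pick <- sample.int(length(set_coords), 1)
  out <- p
  out$coords <- set_coords[[pick]]
  out$orientation <- set_ori[[pick]]
  out$grid_score <- NA_real_
  out$provenance$rotate_set_size <- length(set_coords)
  if (keep_set) out$provenance$rotate_set <- set_heavy
  out
}

#' Slide-Together step
#'
#' Translates the ligand in increments of `step` along the unit vector from
#' its heavy-atom centroid to the receptor center of mass, for as long as
#' the full-atom clash count stays zero. Stops just before the first
#' clashing step, or once the centroid comes within `step` of the center of
#' mass. A ligand that clashes on entry is returned unchanged with the
#' `"slide_blocked"` flag. This guarantees receptor contact before
#' refinement: a free-floating ligand scores zero on the contact potential
#' and gives the refinement stage no signal.
#'
#' @param p A [pose()].
#' @param rec A [receptor()].
#' @param params [fa_params()] for the clash criterion.
#' @param step Step size, Angstrom (default 0.1).
#' @return The slid pose; `provenance$slide_steps` records the step count.
#' @export
slide_together <- function(p, rec, params = fa_params(), step = 0.1) {
  stopifnot(step > 0)
  if (count_clashes(p, rec, params) > 0L) {
    p$flags <- union(p$flags, "slide_blocked")
    p$provenance$slide_steps <- 0L
    return(p)
  }
  com <- rec$center_of_mass
  hmask <- p$mol$is_heavy
  coords <- p$coords
  taken <- 0L
  repeat {
    ctr <- centroid(coords[hmask, , drop = FALSE])
    gap <- com - ctr
    dist <- sqrt(sum(gap^2))
    if (dist <= step) break
    cand <- sweep(coords, 2, gap / dist * step, "+")
    if (count_clashes(cand[hmask, , drop = FALSE], rec, params,
                      mol = NULL) > 0L) break
    coords <- cand
    taken <- taken + 1L
  }
  p$coords <- coords
  p$grid_score <- NA_real_
  p$fa_score <- NA_real_
  p$provenance$slide_steps <- taken
  p
}

#' Legacy three-step initial placement (TransRot)
#'
#' Runs Translate, Rotate and Slide-Together in sequence from
#' `cfg$start_coord`. The Translate step only probes the grid with the
#' ligand's geometric-center atom, and the Rotate step then searches for
#' non-clashing orientations at the translated position — the two stages
#' are independent, which is precisely the limitation that motivates the
#' Transform sampler for elongated ligands and narrow pockets.
#'
#' @param mol A [molecule()].
#' @param rec A [receptor()].
#' @param grid Scoring grid built around the binding site.
#' @param cfg [placement_config()].
#' @param params [fa_params()] for the Slide-Together clash test.
#' @param seed Optional integer seed (sets the global RNG).
#' @param state_log Optional [make_state_log()]: RMSDs of every sampled
#'   state (all translate and rotate proposals) are appended.
#' @return A [pose()] with `grid_score` set and per-step provenance.
#' @export
transrot_place <- function(mol, rec, grid, cfg = placement_config(),
                           params = fa_params(), seed = NULL,
                           state_log = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- pose(mol)
  p <- center_pose_at(p, cfg$start_coord)
  p <- transform_pose(p, random_uniform_rotation())
  p <- translate_step(p, grid, cfg, state_log = state_log)
  p <- rotate_step(p, grid, cfg, state_log = state_log)
  p <- slide_together(p, rec, params, cfg$slide_step)
  p$grid_score <- score_ligand(grid, p)$score
  p$provenance$algorithm <- "transrot"
  p$provenance$seed <- seed
  p
}

#' Metropolis acceptance test
#'
#' Accepts a proposal whose score change `delta` is non-positive; otherwise
#' accepts with probability `exp(-delta / temperature)`. An infinite
#' `delta` (out-of-grid or box-violating proposal) is always rejected.
#'
#' @param delta Score change (proposed - current).
#' @param temperature Positive Monte Carlo temperature.
#' @return Logical.
#' @export
metropolis_accept <- function(delta, temperature = 1.0) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.nan(delta)) return(FALSE)
  if (delta <= 0) return(TRUE)
  if (!is.finite(delta)) return(FALSE)
  stats::runif(1) < exp(-delta / temperature)
}

#' Monte Carlo Metropolis initial placement (Transform)
#'
#' Samples ligand translation, rotation and conformation simultaneously on
#' the scoring grid. The ligand starts at `cfg$start_coord` (conformer 1,
#' one uniform random initial reorientation). Each of the
#' `cfg$transform_cycles` cycles proposes either a conformer swap (with
#' probability `conformer_swap_prob`, when a library is present) or a
#' rigid perturbation of up to `per_move_max_trans` / `per_move_max_angle`
#' — a combined random translation and rotation. A proposal that moves the
#' neighbor atom beyond `box_radius` of the start, or any heavy atom
#' outside the grid, scores `+Inf` and is rejected by the Metropolis test;
#' otherwise the grid score decides. After all cycles the best-scoring
#' visited state is returned. The receptor is rigid throughout; only grid
#' lookups are used for scoring, which is what makes the 500-cycle walk
#' cheap.
#'
#' @param mol A [molecule()].
#' @param rec A [receptor()] (used only for provenance/fingerprint here).
#' @param grid Scoring grid.
#' @param cfg [placement_config()].
#' @param seed Optional integer seed.
#' @param native Optional n x 3 heavy-atom coordinates of the native pose;
#'   when given, per-cycle RMSDs are recorded in the trajectory.
#' @return List with `pose` (best-scoring visited state; flagged
#'   `"transform_failed"` if no finite-score state was ever reached) and
#'   `trajectory` (a `mc_trajectory` data.frame: cycle, move, proposed and
#'   current score, acceptance flag, RMSD when `native` is given).
#' @export
transform_place <- function(mol, rec, grid, cfg = placement_config(),
                            seed = NULL, native = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hmask <- mol$is_heavy
  nb_pos <- which(which(hmask) == mol$neighbor_atom)  # row in heavy coords
  n_conf <- length(mol$conformers)
  swaps_on <- n_conf > 1 && cfg$conformer_swap_prob > 0

  p <- pose(mol)
  p <- center_pose_at(p, cfg$start_coord)
  p <- transform_pose(p, random_uniform_rotation())
  cur_score <- transform_score(grid, p, nb_pos, cfg)
  best <- p; best_score <- cur_score

  n <- cfg$transform_cycles
  move <- character(n); prop_s <- numeric(n); acc <- logical(n)
  cur_s <- numeric(n); rms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    do_swap <- swaps_on && stats::runif(1) < cfg$conformer_swap_prob
    if (do_swap) {
      k <- sample.int(n_conf, 1)
      cand <- swap_conformer(p, k)
      move[i] <- "conformer"
    } else {
      pert <- rand_perturbation(cfg$per_move_max_trans, cfg$per_move_max_angle)
      cand <- pose_rigid_move(p, pert$R, pert$t)
      move[i] <- "rigid"
    }
    s <- transform_score(grid, cand, nb_pos, cfg)
    accept <- if (is.infinite(s)) FALSE
              else if (is.infinite(cur_score)) TRUE
              else metropolis_accept(s - cur_score, cfg$mc_temperature)
    if (accept) {
      p <- cand
      cur_score <- s
      # <= : among tied best-scoring states keep the most recent one. The
      # grid score is 3-valued, so large tied plateaus are the norm; the
      # first state to reach the plateau is systematically the shallowest
      # insertion along the approach path, while the latest is an unbiased
      # draw from the plateau explored by the walk.
      if (s <= best_score) { best <- p; best_score <- s }
    }
    prop_s[i] <- s; acc[i] <- accept; cur_s[i] <- cur_score
    if (!is.null(native)) {
      rms[i] <- ligand_rmsd(native, p$coords[hmask, , drop = FALSE])
    }
  }
  best$grid_score <- best_score
  best$provenance$algorithm <- "transform"
  best$provenance$seed <- seed
  if (!is.finite(best_score)) {
    best$flags <- union(best$flags, "transform_failed")
  }
  traj <- data.frame(cycle = seq_len(n), move = move, proposed_score = prop_s,
                     accepted = acc, current_score = cur_s, rmsd = rms)
  class(traj) <- c("mc_trajectory", class(traj))
  attr(traj, "best_score") <- best_score
  list(pose = best, trajectory = traj)
}

# Grid score with the Transform sampler's box constraint folded in.
transform_score <- function(grid, p, nb_pos, cfg) {
  hx <- p$coords[p$mol$is_heavy, , drop = FALSE]
  if (sqrt(sum((hx[nb_pos, ] - cfg$start_coord)^2)) > cfg$box_radius) {
    return(Inf)
  }
  per <- grid_lookup(grid, hx)
  if (anyNA(per)) Inf else as.numeric(sum(per))
}

#' Generate one placement with either algorithm
#'
#' Convenience dispatcher used by the benchmark harness and the
#' command-line interface.
#'
#' @param algorithm `"transrot"` or `"transform"`.
#' @inheritParams transrot_place
#' @param native Optional native heavy-atom coordinates (trajectory RMSDs).
#' @return A [pose()].
#' @export
place_ligand <- function(mol, rec, grid, algorithm = c("transform", "transrot"),
                         cfg = placement_config(), params = fa_params(),
                         seed = NULL, native = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "transrot") {
    transrot_place(mol, rec, grid, cfg, params, seed)
  } else {
    transform_place(mol, rec, grid, cfg, seed, native)$pose
  }
}
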