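# shared fixture: a small imprint complex with a flexible ligand
local_complex <- function(pocket = "imprint", rb = 0, seed = 2, n = 8) {
  make_synthetic_complex(pocket, n_atoms = n, n_rotbonds = rb, seed = seed)
}

test_that("translate_step accepts the first attractive-or-neutral probe", {
  cx <- local_complex()
  # start inside the pocket: every nearby cell is attractive/neutral, so
  # the very first proposal must be accepted
  cfg1 <- cx$cfg
  cfg1$start_coord <- colMeans(cx$native_heavy)
  cfg1$translate_radius <- 0.3  # every probe stays deep in the pocket
  p0n <- griddock:::center_pose_at(pose(cx$ligand), cfg1$start_coord)
  set.seed(4)
  out <- translate_step(p0n, cx$grid, cfg1)
  expect_identical(out$provenance$translate_attempts_used, 1L)
  expect_false("translate_failed" %in% out$flags)
})

test_that("translate_step exhausts its budget on a hopeless grid", {
  cx <- local_complex()
  # an all-repulsive grid: every probe fails, failure is flagged not raised
  rec1 <- receptor("C", matrix(0, 1, 3), backbone = TRUE)
  g_rep <- build_classic_grid(rec1, c(0, 0, 0), side = 4, spacing = 0.5)
  cfg <- placement_config(start_coord = c(0, 0, 0), translate_radius = 0.5)
  p0 <- pose(cx$ligand)
  p0 <- griddock:::center_pose_at(p0, c(0, 0, 0))
  set.seed(9)
  out <- translate_step(p0, g_rep, cfg)
  expect_true("translate_failed" %in% out$flags)
  expect_identical(out$provenance$translate_attempts_used, cfg$translate_attempts)
})

test_that("translate_step with zero radius degenerates to the start cell test", {
  cx <- local_complex()
  cfg <- cx$cfg
  cfg$translate_radius <- 0
  cfg$start_coord <- colMeans(cx$native_heavy)
  p0 <- pose(cx$ligand)
  p0 <- griddock:::center_pose_at(p0, cfg$start_coord)
  set.seed(3)
  out <- translate_step(p0, cx$grid, cfg)
  expect_equal(out$coords, p0$coords)
  expect_false("translate_failed" %in% out$flags)  # start cell is attractive
})

test_that("rotate_step builds a diverse non-clashing set of the right size", {
  for (rb in c(0L, 2L)) {
    cx <- local_complex(rb = rb, seed = 4)
    cfg <- cx$cfg
    cfg$start_coord <- colMeans(cx$native_heavy)
    p0 <- pose(cx$ligand)
    p0 <- griddock:::center_pose_at(p0, cfg$start_coord)
    set.seed(17)
    out <- rotate_step(p0, cx$grid, cfg, keep_set = TRUE)
    target <- max(5L, 5L * length(cx$ligand$rotatable_bonds))
    expect_identical(target, max(5L, 5L * rb))
    set <- out$provenance$rotate_set
    expect_gt(length(set), 0)
    expect_lte(length(set), target)
    floor_rmsd <- 0.65 * sqrt(sum(cx$ligand$is_heavy))
    for (a in seq_along(set)) {
      acc <- check_rotate_acceptance(cx$grid, set[[a]])
      expect_true(acc$accept)
      expect_gte(acc$frac_attractive, 0.85)
      expect_equal(acc$frac_repulsive, 0)
      for (b in seq_len(a - 1)) {
        expect_gt(ligand_rmsd(set[[a]], set[[b]]), floor_rmsd)
      }
    }
  }
})

test_that("rotate_step flags failure in open space", {
  # all-neutral grid: no orientation can reach 85% attractive
  rec_far <- receptor("C", matrix(c(500, 0, 0), 1, 3), backbone = FALSE)
  g0 <- build_classic_grid(rec_far, c(500, 0, 0), side = 40, spacing = 1)
  lig <- make_synthetic_ligand(6, "rod")
  p0 <- pose(lig)
  p0 <- griddock:::center_pose_at(p0, c(500, 15, 0))
  cfg <- placement_config(start_coord = c(500, 15, 0))
  set.seed(2)
  out <- rotate_step(p0, g0, cfg)
  expect_true("rotate_failed" %in% out$flags)
  expect_identical(out$provenance$rotate_set_size, 0L)
  expect_equal(out$coords, p0$coords)
})

test_that("slide_together stops at contact, the COM, or a blocked entry", {
  cx <- local_complex(pocket = "open_shelf", seed = 6)
  lig <- cx$ligand
  com <- cx$receptor$center_of_mass

  # approach from above: must stop clash-free with the next step clashing
  p0 <- pose(lig)
  p0 <- griddock:::center_pose_at(p0, com + c(0, 0, 9))
  out <- slide_together(p0, cx$receptor, step = 0.1)
  expect_identical(count_clashes(out, cx$receptor), 0L)
  ctr <- colMeans(out$coords[lig$is_heavy, , drop = FALSE])
  gap <- com - ctr
  one_more <- out$coords
  one_more <- griddock:::row_shift(one_more, gap / sqrt(sum(gap^2)) * 0.1)
  at_com <- sqrt(sum(gap^2)) <= 0.1
  expect_true(at_com ||
                count_clashes(one_more[lig$is_heavy, , drop = FALSE],
                              cx$receptor) > 0)

  # free path with no obstacle in between: centroid reaches the COM
  # (two distant atoms whose unweighted centroid sits in empty space)
  rec_far <- receptor(c("C", "C"), rbind(c(0, 0, -300), c(0, 0, -100)),
                      backbone = c(FALSE, FALSE))
  p1 <- pose(lig)
  p1 <- griddock:::center_pose_at(p1, c(0, 0, -190))
  out1 <- slide_together(p1, rec_far, step = 0.1)
  ctr1 <- colMeans(out1$coords[lig$is_heavy, , drop = FALSE])
  expect_lte(sqrt(sum((ctr1 - rec_far$center_of_mass)^2)), 0.1 + 1e-9)

  # already clashing at entry: unchanged, flagged
  p2 <- pose(lig)
  p2 <- griddock:::center_pose_at(p2, cx$receptor$coords[1, ])
  out2 <- slide_together(p2, cx$receptor, step = 0.1)
  expect_true("slide_blocked" %in% out2$flags)
  expect_equal(out2$coords, p2$coords)
})

test_that("metropolis_accept follows the canonical criterion", {
  expect_true(metropolis_accept(-1, 1))
  expect_true(metropolis_accept(0, 1))
  expect_false(metropolis_accept(Inf, 1))
  expect_error(metropolis_accept(1, 0), "positive")
  set.seed(10)
  n <- 2e4
  acc <- sum(vapply(seq_len(n), function(i) metropolis_accept(1, 1), TRUE))
  expect_lt(abs(acc / n - exp(-1)), 0.02)
})

test_that("both placement algorithms are bit-deterministic given a seed", {
  cx <- local_complex(rb = 1, seed = 8)
  a <- transrot_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 33)
  b <- transrot_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 33)
  expect_identical(a$coords, b$coords)
  expect_identical(a$flags, b$flags)

  r1 <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 33)
  r2 <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 33)
  expect_identical(r1$pose$coords, r2$pose$coords)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("transform sampler honors its contracts", {
  cx <- local_complex(rb = 2, seed = 5)
  res <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 21)
  tr <- res$trajectory
  # returned pose is the best-scoring accepted state
  acc_scores <- tr$current_score[is.finite(tr$current_score)]
  expect_lte(res$pose$grid_score, min(acc_scores))
  expect_identical(res$pose$grid_score, attr(tr, "best_score"))
  expect_identical(res$pose$grid_score,
                   score_ligand(cx$grid, res$pose)$score)
  # neighbor atom stays inside the sampling box, all atoms inside the grid
  nb <- cx$ligand$neighbor_atom
  expect_lte(sqrt(sum((res$pose$coords[nb, ] - cx$cfg$start_coord)^2)),
             cx$cfg$box_radius)
  expect_true(all(!is.na(
    score_ligand(cx$grid, res$pose)$per_atom)))
  # best score never exceeds the initial state's score
  first_finite <- tr$current_score[1]
  expect_lte(res$pose$grid_score, first_finite)
})

test_that("near-zero temperature makes the transform walk greedy", {
  cx <- local_complex(seed = 3)
  cfg <- cx$cfg
  cfg$mc_temperature <- 1e-9
  res <- transform_place(cx$ligand, cx$receptor, cx$grid, cfg, seed = 12)
  cs <- res$trajectory$current_score
  cs <- cs[is.finite(cs)]
  expect_true(all(diff(cs) <= 0))
})

test_that("accepted transform states preserve ligand internal geometry", {
  cx <- local_complex(rb = 2, seed = 9)
  res <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 40)
  p <- res$pose
  ref <- cx$ligand$conformers[[p$conformer]]
  expect_lt(max(abs(dist(p$coords) - dist(ref))), 1e-6)
})

test_that("transrot composes its three steps and records provenance", {
  cx <- local_complex(pocket = "rod_channel", seed = 1)
  p <- transrot_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 2)
  expect_identical(p$provenance$algorithm, "transrot")
  expect_true(!is.null(p$provenance$translate_attempts_used))
  expect_true(!is.null(p$provenance$slide_steps))
  expect_true(is.finite(p$grid_score) || "rotate_failed" %in% p$flags ||
                "translate_failed" %in% p$flags)
})
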