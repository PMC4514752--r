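test_that("count_clashes applies the overlap criterion", {
  lig <- matrix(c(0, 0, 0), 1, 3)
  rec_far <- receptor("C", matrix(c(10, 0, 0), 1, 3), backbone = FALSE)
  expect_identical(count_clashes(lig, rec_far), 0L)

  # C-C pair at 2.0 A with tolerance 0.6: 2.0 < 1.7 + 1.7 - 0.6 = 2.8
  rec_close <- receptor("C", matrix(c(2, 0, 0), 1, 3), backbone = FALSE)
  expect_identical(count_clashes(lig, rec_close), 1L)
  # just outside the limit
  rec_edge <- receptor("C", matrix(c(2.81, 0, 0), 1, 3), backbone = FALSE)
  expect_identical(count_clashes(lig, rec_edge), 0L)
})

test_that("count_clashes equals the brute-force all-pairs count", {
  set.seed(61)
  params <- fa_params()
  for (rep in 1:5) {
    rec <- make_random_receptor(40, box = 10)
    lig_xyz <- matrix(runif(18, -5, 5), 6, 3)
    brute <- 0L
    for (i in 1:6) {
      for (j in seq_len(40)) {
        d <- sqrt(sum((lig_xyz[i, ] - rec$coords[j, ])^2))
        if (d < 1.7 + 1.7 - params$clash_tolerance) brute <- brute + 1L
      }
    }
    expect_identical(count_clashes(lig_xyz, rec, params), brute)
  }
})

test_that("fa_score is zero when separated and -w_atr at exact contact", {
  lig <- matrix(0, 1, 3)
  rec_far <- receptor("C", matrix(c(30, 0, 0), 1, 3), backbone = FALSE)
  expect_identical(fa_score(lig, rec_far), 0)

  rec_contact <- receptor("C", matrix(c(3.4, 0, 0), 1, 3), backbone = FALSE)
  expect_equal(fa_score(lig, rec_contact), -fa_params()$w_atr)
})

test_that("fa_score is continuous with consistent finite differences", {
  set.seed(71)
  rec <- make_random_receptor(25, box = 8)
  lig_xyz <- matrix(runif(12, -4, 4), 4, 3)
  params <- fa_params()
  s0 <- fa_score(lig_xyz, rec, params)
  # continuity: epsilon displacement changes the score by O(epsilon)
  for (eps in c(1e-3, 1e-5)) {
    s1 <- fa_score(griddock:::row_shift(lig_xyz, c(eps, 0, 0)), rec, params)
    expect_lt(abs(s1 - s0), 100 * eps + 1e-12)
  }
  # two-sided difference quotients at h and h/10 agree (smoothness away
  # from the well kinks): central difference is O(h^2)
  h <- 1e-3
  num_g <- function(h) {
    (fa_score(griddock:::row_shift(lig_xyz, c(h, 0, 0)), rec, params) -
       fa_score(griddock:::row_shift(lig_xyz, c(-h, 0, 0)), rec, params)) / (2 * h)
  }
  expect_lt(abs(num_g(h) - num_g(h / 10)), 1e-2)
})

test_that("rigid_minimize descends into a constructed well", {
  # single receptor atom, single ligand atom: the score minimum is at the
  # contact distance 3.4 A
  rec <- receptor("C", matrix(0, 1, 3), backbone = FALSE)
  lig <- molecule("C", matrix(c(3.7, 0, 0), 1, 3), NULL)
  p <- pose(lig)
  out <- rigid_minimize(p, rec)
  expect_lte(out$fa_score, fa_score(p, rec))
  expect_lt(abs(sqrt(sum(out$coords^2)) - 3.4), 0.05)

  # a pose already at the minimum stays put
  lig2 <- molecule("C", matrix(c(3.4, 0, 0), 1, 3), NULL)
  out2 <- rigid_minimize(pose(lig2), rec)
  expect_lt(max(abs(out2$coords - lig2$coords)), 0.05)
})

test_that("rigid_minimize never increases the score", {
  set.seed(81)
  cx <- make_synthetic_complex("imprint", n_atoms = 8, seed = 14)
  for (s in 1:5) {
    p <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = s)$pose
    before <- fa_score(p, cx$receptor)
    after <- rigid_minimize(p, cx$receptor)
    expect_lte(after$fa_score, before + 1e-12)
    expect_equal(after$fa_score, fa_score(after, cx$receptor))
  }
})

test_that("refine_min selects the viable conformer then minimizes", {
  # single conformer: refine_min is exactly rigid_minimize
  rec <- receptor("C", matrix(0, 1, 3), backbone = FALSE)
  lig <- molecule("C", matrix(c(3.8, 0, 0), 1, 3), NULL)
  p <- pose(lig)
  expect_equal(refine_min(p, rec)$coords, rigid_minimize(p, rec)$coords)

  # two conformers, one driven into the wall: the unblocked one wins.
  # A two-atom ligand with an extended and a "bent-back" conformer placed
  # against a flat wall of atoms.
  wall <- as.matrix(expand.grid(x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = 0))
  recw <- receptor(rep("C", nrow(wall)), wall, backbone = rep(FALSE, nrow(wall)))
  ext <- rbind(c(0, 0, 3.4), c(0, 1.5, 3.4))      # parallel to the wall
  blocked <- rbind(c(0, 0, 3.4), c(0, 0, 1.0))    # second atom in the wall
  lig2 <- molecule(c("C", "C"), ext, data.frame(from = 1, to = 2, order = 1L),
                   conformers = list(blocked))
  p2 <- pose(lig2, conformer = 1)
  sel <- griddock:::select_best_conformer(p2, recw, fa_params())
  expect_identical(sel$conformer, 1L)
  out <- refine_min(p2, recw)
  expect_lte(out$fa_score, fa_score(p2, recw))
})

test_that("refine_mcm keeps the best of its schedule and is deterministic", {
  cx <- make_synthetic_complex("imprint", n_atoms = 8, n_rotbonds = 2, seed = 14)
  p <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 3)$pose
  entry <- fa_score(p, cx$receptor)
  set.seed(55)
  a <- refine_mcm(p, cx$receptor)
  set.seed(55)
  b <- refine_mcm(p, cx$receptor)
  expect_identical(a$coords, b$coords)
  expect_lte(a$fa_score, entry + 1e-12)
})

test_that("refinement preserves internal geometry up to conformer swaps", {
  cx <- make_synthetic_complex("imprint", n_atoms = 8, n_rotbonds = 2, seed = 14)
  p <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 6)$pose
  out <- refine_min(p, cx$receptor)
  ref <- cx$ligand$conformers[[out$conformer]]
  expect_lt(max(abs(dist(out$coords) - dist(ref))), 1e-6)
})
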