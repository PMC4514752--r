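test_that("repulsive and attractive shells classify cells as specified", {
  # single backbone atom at the grid center
  rec <- receptor("C", matrix(0, 1, 3), backbone = TRUE)
  g <- build_classic_grid(rec, c(0, 0, 0), side = 10, spacing = 0.25)
  expect_identical(score_point(g, c(1.0, 0, 0)), 1L)   # inside repulsive sphere
  expect_identical(score_point(g, c(3.0, 0, 0)), -1L)  # attractive band
  expect_identical(score_point(g, c(4.9, 0, 0)), 0L)   # beyond both shells

  # side-chain heavy atom: never repulsive, still attractive
  rec2 <- receptor("C", matrix(0, 1, 3), backbone = FALSE)
  g2 <- build_classic_grid(rec2, c(0, 0, 0), side = 13, spacing = 0.25)
  expect_identical(score_point(g2, c(1.0, 0, 0)), 0L)
  expect_identical(score_point(g2, c(3.0, 0, 0)), -1L)
  expect_identical(score_point(g2, c(6.0, 0, 0)), 0L)
})

test_that("grid agrees with the brute-force distance classifier", {
  set.seed(31)
  rec <- make_random_receptor(30)
  g <- build_classic_grid(rec, c(0, 0, 0), side = 6, spacing = 0.5)
  expect_identical(g$values, brute_force_grid_values(rec, g))
})

test_that("cell lookup uses the floor convention and an out-of-grid sentinel", {
  rec <- receptor("C", matrix(100, 1, 3), backbone = TRUE)
  g <- build_classic_grid(rec, c(100, 100, 100), side = 4, spacing = 0.5)
  # a point exactly on a cell boundary belongs to the higher-index cell
  p_boundary <- g$origin + c(0.5, 0.2, 0.2)
  i <- floor((p_boundary - g$origin) / g$spacing) + 1
  expect_equal(i[1], 2)
  expect_identical(score_point(g, p_boundary),
                   g$values[matrix(i, ncol = 3)])
  expect_identical(score_point(g, g$origin - 1), OUT_OF_GRID)
  expect_identical(score_point(g, g$origin + c(10, 0, 0)), OUT_OF_GRID)
})

test_that("ligand grid score sums heavy atoms and rejects out-of-grid poses", {
  rec <- receptor("C", matrix(0, 1, 3), backbone = FALSE)
  g <- build_classic_grid(rec, c(0, 0, 0), side = 10, spacing = 0.25)
  on_shell <- sweep(3.2 * diag(3), 2, c(0, 0, 0), "+")
  on_shell <- rbind(on_shell, -3.2 * diag(3))[1:5, ]
  res <- score_ligand(g, on_shell)
  expect_identical(res$score, -5)
  expect_identical(res$per_atom, rep(-1L, 5))

  outside <- rbind(on_shell, c(50, 0, 0))
  expect_identical(score_ligand(g, outside)$score, Inf)
})

test_that("the rotate acceptance rule enforces its two thresholds", {
  # synthetic per-atom layout via a grid made of known cells: use a wide
  # attractive field plus controlled probe points
  rec <- receptor(rep("C", 2), rbind(c(0, 0, 0), c(20, 0, 0)),
                  backbone = c(FALSE, TRUE))
  g <- build_classic_grid(rec, c(10, 0, 0), side = 28, spacing = 0.5)
  attr_pt <- c(3.0, 0, 0)    # attractive
  neut_pt <- c(10, 3, 0)     # neutral
  rep_pt <- c(20.5, 0, 0)    # repulsive (near the backbone atom)

  x9of10 <- rbind(matrix(rep(attr_pt, 9), ncol = 3, byrow = TRUE) +
                    cbind(0, seq(-2, 2, length.out = 9) * 0.1, 0), neut_pt)
  r <- check_rotate_acceptance(g, x9of10)
  expect_true(r$accept)
  expect_equal(r$frac_attractive, 0.9)

  with_clash <- rbind(x9of10[1:9, ], rep_pt)
  r2 <- check_rotate_acceptance(g, with_clash)
  expect_false(r2$accept)
  expect_gt(r2$frac_repulsive, 0)

  x8of10 <- rbind(x9of10[1:8, ], neut_pt, neut_pt + c(0, 0.5, 0))
  expect_false(check_rotate_acceptance(g, x8of10)$accept)
})

test_that("grid construction is deterministic and radius-monotone", {
  set.seed(77)
  rec <- make_random_receptor(20)
  g1 <- build_classic_grid(rec, c(0, 0, 0), side = 8, spacing = 0.5)
  g2 <- build_classic_grid(rec, c(0, 0, 0), side = 8, spacing = 0.5)
  expect_identical(g1, g2)

  # enlarging the attractive outer radius only converts neutral cells to
  # attractive; repulsive cells are untouched
  g3 <- build_classic_grid(rec, c(0, 0, 0), side = 8, spacing = 0.5,
                           attractive_radius = 5.75)
  expect_identical(which(g1$values == 1L), which(g3$values == 1L))
  was_attr <- g1$values == -1L
  expect_true(all(g3$values[was_attr] == -1L))
  changed <- g1$values != g3$values
  expect_true(all(g1$values[changed] == 0L & g3$values[changed] == -1L))
})

test_that("the grid auto-expands when the ligand cannot stay inside", {
  rec <- make_random_receptor(10)
  lig <- make_synthetic_ligand(10, "rod")
  expect_warning(
    g <- build_classic_grid(rec, c(0, 0, 0), side = 10, spacing = 0.5,
                            ligand = lig, translate_radius = 5),
    "expanding")
  extent <- max(dist(lig$coords))
  expect_gte(g$dims[1] * g$spacing, extent + 2 * 5)
})

test_that("the grid manager weights member grids and detects staleness", {
  set.seed(13)
  rec <- make_random_receptor(12)
  g <- build_classic_grid(rec, c(0, 0, 0), side = 8, spacing = 0.5)
  mgr <- grid_manager(rec, list(classic = g), weights = 2)
  probe <- matrix(c(0.3, 0.2, 0.1), 1, 3)
  expect_identical(score_manager(mgr, rec, probe),
                   2 * score_ligand(g, probe)$score)

  moved <- rec
  moved$coords[1, ] <- moved$coords[1, ] + 0.5
  expect_error(score_manager(mgr, moved, probe), "changed")
  expect_error(grid_manager(rec, list(g)), "named")
})

test_that("grid serialization round-trips exactly", {
  set.seed(21)
  rec <- make_random_receptor(10)
  g <- build_classic_grid(rec, c(0, 0, 0), side = 6, spacing = 0.5)
  path <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, path, fingerprint = receptor_fingerprint(rec))
  back <- read_grid(path)
  expect_identical(back$values, g$values)
  expect_equal(back$origin, g$origin)
  expect_equal(back$spacing, g$spacing)
  expect_equal(attr(back, "fingerprint"), receptor_fingerprint(rec))
})
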