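# Fixtures built in code: tiny molecules, receptors and file snippets.

# butane: 4 carbons in a line, one rotatable bond (C2-C3)
make_butane <- function() {
  molecule(rep("C", 4), cbind(c(0, 1.5, 3.0, 4.5), 0, 0),
           data.frame(from = 1:3, to = 2:4, order = 1L), name = "butane")
}

# benzene: 6-ring, alternating bond orders, no rotatable bonds
make_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  molecule(rep("C", 6), cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
           data.frame(from = 1:6, to = c(2:6, 1), order = rep(c(1L, 2L), 3)),
           name = "benzene")
}

# a single-chain pseudo-receptor of n heavy atoms scattered in a box,
# with a configurable fraction flagged as backbone
make_random_receptor <- function(n = 30, backbone_frac = 0.5, box = 8) {
  coords <- matrix(stats::runif(3 * n, -box / 2, box / 2), n, 3)
  receptor(rep("C", n), coords,
           backbone = seq_len(n) <= round(backbone_frac * n),
           atom_names = ifelse(seq_len(n) <= round(backbone_frac * n),
                               "CA", "CB"))
}

# 3-residue toy PDB text: 4 backbone + (2,3,3)=8 additional side-chain
# heavy atoms -> 12 backbone-masked of 20 atoms
toy_pdb_lines <- function() {
  atoms <- list()
  idx <- 0
  for (res in 1:3) {
    base <- c(4 * res, 0, 0)
    bb <- list(N = c(0, 0, 0), CA = c(1.4, 0.3, 0), C = c(2.4, -0.6, 0),
               O = c(2.4, -1.8, 0))
    sc_names <- list(c("CB", "CG"), c("CB", "CG", "SD"), c("CB", "OG", "CD"))[[res]]
    sc <- lapply(seq_along(sc_names), function(k) c(1.4, 1.5 * k, 0.5))
    names(sc) <- sc_names
    for (nm in names(c(bb, sc))) {
      idx <- idx + 1
      xyz <- base + c(bb, sc)[[nm]]
      el <- substr(nm, 1, 1)
      atoms[[idx]] <- sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        idx, nm, res, xyz[1], xyz[2], xyz[3], el)
    }
  }
  unlist(atoms)
}

write_toy_pdb <- function(extra_lines = character()) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(c(toy_pdb_lines(), extra_lines, "END"), path)
  path
}

# brute-force reference classifier for the binary grid: O(cells x atoms)
brute_force_grid_values <- function(rec, grid,
                                    repulsive_radius = 2.25,
                                    attractive_radius = 4.75) {
  dims <- grid$dims
  vals <- array(0L, dims)
  hv <- which(rec$is_heavy)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        ctr <- grid$origin + (c(i, j, k) - 0.5) * grid$spacing
        d <- sqrt(colSums((t(rec$coords[hv, , drop = FALSE]) - ctr)^2))
        if (any(d[rec$backbone[hv]] <= repulsive_radius)) {
          vals[i, j, k] <- 1L
        } else if (any(d >= repulsive_radius & d <= attractive_radius)) {
          vals[i, j, k] <- -1L
        }
      }
    }
  }
  vals
}
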