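Package: griddock
Title: Grid-Scored Ligand Placement and Rigid-Body Docking Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Low-resolution protein-ligand docking machinery built around
    binary attractive/repulsive Cartesian scoring grids. Implements the
    legacy three-step initial placement protocol (random translation,
    diverse-set rotation, slide-together) and a Metropolis Monte Carlo
    placement sampler that perturbs ligand position, orientation and
    conformer simultaneously on the grid, followed by simplified rigid-body
    refinement against a soft-sphere contact score. Includes a synthetic
    pocket/ligand fixture generator with known native poses and a
    success-rate benchmarking harness (lowest-scoring-model RMSD criterion
    with random subsampling over model budgets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    bio3d,
    ChemmineR,
    generics,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
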