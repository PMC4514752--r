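# griddock

Low-resolution protein–ligand docking machinery in R: binary
attractive/repulsive scoring grids, two initial-placement algorithms, a
simplified rigid-body refinement stage, and a success-rate benchmarking
harness that runs end-to-end on synthetic protein/ligand fixtures with
known native poses.

## The problem

Two-stage docking pipelines place a ligand in the binding site first and
refine it second. Refinement is local, so everything hinges on the initial
placement. The classic placement protocol (here **TransRot**) translates
and rotates the ligand in *separate* stages: up to 50 random translations
within 5 Å of a start coordinate, probing only the ligand's
geometric-center atom ("neighbor atom") on the grid; then up to 500 random
reorientations, accumulating a diverse set of clash-free orientations (no
atom in a repulsive cell, ≥ 85 % of atoms in attractive cells, pairwise
RMSD > 0.65·√n_heavy), of which one is returned at random; then a
Slide-Together step that pushes the ligand toward the receptor center of
mass until just before steric contact is lost to a clash. Because
translation knows nothing about orientation, an elongated ligand facing a
narrow channel is routinely translated somewhere it can never be rotated
into — the motivating failure mode.

The **Transform** algorithm replaces the split stages with a single
Metropolis Monte Carlo walk over translation, rotation *and* ligand
conformation. Each of 500 cycles proposes either a small rigid move
(≤ 0.5 Å, ≤ 30°) or a swap to a random library conformer; the proposal is
scored on the grid (cells: +1 repulsive within 2.25 Å of backbone heavy
atoms, −1 attractive within 2.25–4.75 Å of any heavy atom, 0 neutral; any
atom outside the grid or a neighbor atom outside the 5 Å sampling box
scores +∞), and accepted with probability min(1, exp(−ΔE/T)). The
best-scoring visited state becomes the placement. Refinement then scores a
soft-sphere contact potential (quadratic overlap penalty + triangular
contact well on heavy-atom pairs) with either a single rigid-body
minimisation (**MIN**) or a six-step perturb/minimise schedule (**MCM**),
keeping the best pose. A docking run is judged successful when the
lowest-scoring of a budget of models lies within 2.0 Å heavy-atom RMSD
(fixed frame, no superposition) of the native pose.

See `vignettes/griddock-methods.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

```r
library(griddock)

# a rod-shaped 8-carbon ligand in a narrow channel pocket, native pose known
cx <- make_synthetic_complex("rod_channel", n_atoms = 8, seed = 3)
cx$grid
#> scoring_grid: 89 x 89 x 89 cells, 0.25 A spacing
#>   attractive 234869, neutral 281663, repulsive 188437

# Monte Carlo placement
res <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg,
                       seed = 7, native = cx$native_heavy)
res$pose$grid_score        # -8: all 8 heavy atoms in attractive cells
pose_rmsd(res$pose, cx$native_heavy)
#> [1] 5.32                 # in the channel, but entered the wrong way round

# legacy three-step placement on the same seed
p2 <- transrot_place(cx$ligand, cx$receptor, cx$grid, cx$cfg, seed = 7)
pose_rmsd(p2, cx$native_heavy)
#> [1] 8.93                 # translated outside, rotation set empty, flagged
p2$flags
#> [1] "slide_blocked"
```

A grid score of −8 means every heavy atom sits in the favourable-contact
band; single placements still often enter the near-symmetric channel
end-for-end (RMSD ≈ 5–8 Å), which is why protocols generate many models
and let the refinement score choose:

```r
cxi <- make_synthetic_complex("imprint", n_atoms = 8, n_rotbonds = 1, seed = 11)
m <- generate_models(cxi, 150, "transform", "min", seed = 231)
m$rmsd[which.min(m$fa_score)]   # RMSD of the lowest-scoring model
#> [1] 0.48                      # native pose recovered

bm <- run_benchmark(list(cxi), "transform", "min",
                    n_models = 50, budgets = c(10, 25, 50), seed = 1)
autoplot(bm)                    # success fraction vs model budget
```

A command-line front end with `make-grid`, `synth`, `place`, `refine` and
`benchmark` subcommands is installed at `inst/scripts/griddock`.

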