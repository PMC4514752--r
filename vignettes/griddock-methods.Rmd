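---
title: "Grid-scored ligand placement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-scored ligand placement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(griddock)
```

## The problem

Protein–ligand docking is usually run in two stages: an *initial placement*
stage that deposits the ligand somewhere plausible in the binding site, and
a *refinement* stage that polishes that placement against a detailed score.
Refinement is local: if the initial placement is wrong — wrong entrance,
wrong orientation, wrong end of a channel — no amount of polishing
recovers the native pose. griddock implements and compares two initial
placement strategies on a shared scoring infrastructure, together with a
simplified refinement stage and a benchmarking harness that measures how
often a docking protocol recovers a known native pose as its
lowest-scoring model.

## The binary scoring grid

Both placement algorithms score ligand positions on a precomputed Cartesian
grid rather than on atom-pair potentials, which is what makes thousands of
pose evaluations per second possible. The classic grid is binary:

* a cell is **repulsive** (+1) when its center lies within 2.25 Å of any
  *backbone* heavy atom — placing a ligand atom there implies an
  unresolvable main-chain clash;
* otherwise it is **attractive** (−1) when its center lies between 2.25 and
  4.75 Å of *any* receptor heavy atom — the favourable-contact band;
* otherwise **neutral** (0).

A ligand placement is scored as the sum of cell values under its heavy
atoms; any heavy atom outside the grid scores the pose +∞, which makes the
samplers reject grid-escaping moves with no special control path. Cell
values are categorical, so lookup is nearest-cell (floor convention: a
point exactly on a boundary belongs to the higher-index cell) with no
interpolation.

Conventions worth stating because the protocol description leaves them
open: where the repulsive and attractive shells overlap, repulsive wins
(clash safety first); the repulsive region is the solid sphere r ≤ 2.25 Å,
not an annulus; cells are classified by their center point; and the 85%
attractive quota of the Rotate step (below) is counted over heavy atoms
only, since ligands are modelled without hydrogens here. The default cube
is 10 Å × 10 Å × 10 Å at 0.25 Å spacing (a 1000 Å³ volume); because a
ligand translated to the edge of its 5 Å sampling radius must still fit
inside the grid, the builder auto-expands the side to
(ligand extent + 2 × translation radius + 2 Å) with a warning when the
configured side is too small. A `grid_manager` owns named grids with
weights and refuses to score against a receptor whose heavy-atom
coordinates changed since build time (fingerprint check); only the single
classic grid is implemented, but the container is deliberately pluggable.

## TransRot: the legacy three-step placement

1. **Translate** — up to 50 uniform random offsets within 5.0 Å of the
   start coordinate; after each, only the *neighbor atom* (the heavy atom
   closest to the ligand's heavy-atom centroid) is probed on the grid, and
   the first attractive-or-neutral probe is accepted.
2. **Rotate** — up to 500 uniform random reorientations about the
   centroid, accumulating a diverse set of non-clashing orientations: a
   candidate joins the set only if no heavy atom is repulsive, at least
   85% of heavy atoms are attractive, and its fixed-frame RMSD to every
   member already accepted exceeds 0.65·√(n heavy atoms) Å. The target set
   size is max(5, 5 × rotatable bonds); one member is returned uniformly
   at random.
3. **Slide Together** — translate in 0.1 Å steps toward the receptor
   center of mass while the full-atom clash count stays zero, so the
   ligand starts refinement in contact with the receptor.

The translation stage knows nothing about orientation and the rotation
stage cannot move the ligand: an elongated ligand facing a narrow channel
is usually translated into an unenterable position, and the run fails with
a flagged, far-from-native pose. That failure mode is exactly what the
rod-channel fixtures (below) exercise.

## Transform: Metropolis Monte Carlo placement

The Transform sampler treats translation, rotation and conformation as one
move space. Starting from the start coordinate (conformer 1, one uniform
random initial reorientation — the protocol description does not specify
an initial orientation, and an unbiased draw keeps the sampler
self-contained), each of 500 cycles proposes either

* a **rigid perturbation**: a random translation within 0.5 Å combined
  with a rotation of up to 30° about a random axis, or
* a **conformer swap** (probability 0.1, when a library is present): a
  uniformly chosen library conformer re-centered on the current centroid
  with the current cumulative orientation applied.

The proposal is scored on the grid, with +∞ for any heavy atom outside
the grid or a neighbor atom beyond the 5 Å sampling box around the start,
and accepted by the Metropolis criterion at temperature 1.0 on the
grid-score scale. After all cycles the best-scoring visited state is
returned.

Per-cycle move magnitudes, the swap probability and the temperature are
not part of the published protocol constants; the defaults were chosen
once so that a 500-cycle walk can traverse the sampling box (500 moves of
≤0.5 Å give ample mobility across a 10 Å box) and a unit temperature is
natural for a score whose per-atom increments are ±1. All are exposed in
`placement_config()`, and the Metropolis calibration test pins the
acceptance rule independently of the defaults.

Two tie-handling decisions matter on a 3-valued score. First, ties between
equally scoring best states are resolved in favour of the *most recently
visited*: the first state to reach a score plateau is systematically the
shallowest insertion along the approach path, while the latest is an
unbiased draw from the plateau region the walk explored. Second, the
"either/or" wording of the move schedule is implemented literally: a cycle
proposes a conformer swap *or* a rigid move, never both.

A conformer swap must not teleport the ligand: the new conformer is
centered on the current heavy-atom centroid and rotated by the pose's
cumulative orientation matrix (tracked through every rigid move since the
start), so a swap changes internal geometry only. This is simpler and
exactly deterministic compared with aligning principal axes of the two
conformers, and it guarantees the invariant that every visited state is a
rigid transform of some library conformer.

## Surrogate refinement score

The refinement stage of the original pipeline scores with a full atomistic
energy function and repacks protein side chains. Both are out of scope
here: griddock keeps the receptor rigid and scores refinement with a
deliberately simple soft-sphere contact potential over ligand/receptor
heavy-atom pairs,

$$ E = \sum_{ij} \left[ w_{rep}\,\max(0,\; (r_i + r_j - t) - d_{ij})^2
  \;-\; w_{atr}\,\max\!\left(0,\; 1 - \frac{|d_{ij} - (r_i + r_j)|}{w}\right) \right] $$

with van der Waals radii from a fixed built-in element table (Bondi-style
values; carbon 1.70 Å fallback for unknown elements), clash tolerance
t = 0.6 Å, well half-width w = 1.5 Å, and weights 1.0 / 0.25. The form was
chosen for three properties the refinement machinery relies on: zero score
at separation, continuity in the coordinates, and a well minimum exactly
at the contact distance. It is a surrogate, not an approximation of any
specific force field, and the benchmark conclusions are therefore ordered
comparisons between protocols run on the same score, never absolute
energies. Side-chain repacking is replaced by re-selection of the ligand
conformer that minimises the surrogate score at the current placement —
the ligand-side content of a packing cycle.

Two refinement schedules are provided. **MIN** performs one conformer
re-selection followed by a rigid-body minimisation. **MCM** runs six
steps — odd steps re-select and minimise, even steps apply a small random
perturbation (0.1 Å, 20°) — records the pose after every step, keeps the
best-scoring recorded pose and applies a final minimisation. The "best of
the six" comparison uses the pose recorded after each step as-is (the
alternative, comparing only post-minimisation scores, is not what the
schedule description says). The minimiser is a derivative-free pattern
search over the six rigid degrees of freedom (±steps along each
translation axis and ±rotations about each axis through the centroid,
starting at 0.25 Å / 5°, halving on failure, terminating below 0.01 Å or
at 60 iterations). Its contract is descent and convergence, not a
specific optimizer; gradients of the surrogate exist but a pattern search
is robust to the well kinks and cheap at this problem size.

## Synthetic fixtures

There is no experimental benchmark in this package; fixtures are generated
with a known native pose so accuracy is measurable exactly.
`make_synthetic_ligand()` builds all-carbon pseudo-ligands: an extended
zig-zag **rod** (1.5 Å bonds), a **bent** chain with a ~113° elbow, and a
compact **globular** cluster (Fibonacci sphere + minimum-spanning-tree
bonds). The rotatable-bond count (0–3, matching small rigid-ligand
docking sets) is controlled by *restricting* the topologically rotatable
set, emulating conjugation or amide rigidity that a bare connection table
cannot express; conformers are enumerated on a 120° torsion grid with a
self-clash filter (non-bonded pairs closer than 0.7 × radius sum, 1-2/1-3
pairs exempt) and capped at 100.

`make_synthetic_complex()` surrounds a native ligand pose with receptor
atoms on shells 3.0–4.5 Å away (inside the attractive band), flagged as
backbone so the walls are repulsive at close range, in four archetypes:
**rod_channel** and **bent_channel** (tubes around the ligand, open at one
end), **imprint** (a moulded shell with an entrance cone), and
**open_shelf** (a flat slab — a shallow, orientation-tolerant site).
Channels and imprints carry a second wall layer at 6.0 Å: a single thin
shell floating in vacuum would have its own attractive halo on the
*outside*, a geometry no buried protein site has, and the outer layer
pushes that halo beyond the sampler's box constraint. The imprint ligand
is bent rather than globular because a moulded shell around a
quasi-spherical cluster cannot encode orientation — the cluster fits its
own imprint in many rotations. The start coordinate is placed ~4 Å from
the native centroid toward the pocket opening with a small seeded jitter
(always within the 5 Å translation reach).

What these fixtures emulate: pocket/ligand shape complementarity, narrow
entrances requiring correct orientation, and a native pose that satisfies
the samplers' own acceptance rules. What they do not emulate: real
chemistry (everything is carbon), electrostatics and hydrogen bonding,
receptor flexibility, solvent, and the conformational diversity of real
druglike ligands. Passing tests therefore demonstrate the *sampling*
claims — simultaneous translation/rotation sampling finds narrow pockets
that split translation/rotation cannot — not chemical accuracy on real
complexes.

## Benchmarking

`run_benchmark()` follows the standard success-rate methodology: generate
a pool of models per complex, and for each model budget *k* draw 20 random
subsamples of size *k*, keep each subsample's lowest-scoring model, and
call the subsample a success when that model is within 2.0 Å heavy-atom
RMSD (fixed frame, identity atom mapping, no symmetry correction) of the
native pose. The curve reports mean ± sd over resamples of the success
fraction across complexes. The default budget grid {10, 25, 50, 100, 150}
brackets the ~150-model convergence point of the grid-scored Monte Carlo
protocol. Budgets are indexed by model count, not wall-clock time, because
per-model timing is hardware-bound. `sampling_enrichment()` measures the
per-state analogue: the fraction of *all* states visited during placement
that lie within the RMSD threshold.

Problem sizes used by the test suite and the acceptance script — chosen as
a desk-scale experiment a reviewer can reproduce in minutes — are 8-atom
ligands, 10 rod-channel complexes × 100 seeded runs for the paired
placement comparison, and 20 replicates of 150 transform+MIN models for
imprint recovery. All comparative claims are asserted as strict ordered
inequalities (Transform > TransRot); absolute success percentages are
properties of a benchmark set and are not portable to synthetic fixtures.

## Other conventions and numerical choices

* The receptor center of mass is the *unweighted* heavy-atom centroid
  (no mass weighting — masses add nothing at this resolution).
* All rotations pivot about the ligand's current heavy-atom centroid,
  keeping translation and rotation decoupled.
* Poses are manipulated purely as Cartesian coordinate lists; a rigid
  move is one matrix multiply plus a shift, and there is no
  internal-coordinate machinery anywhere.
* Uniform rotations are drawn by the normalised-quaternion method;
  small perturbations use a uniform random axis, an angle uniform in
  [0, max], and a translation uniform in the ball.
* Placement failures (no acceptable translation, empty rotation set, no
  finite-score Monte Carlo state) return flagged poses rather than
  raising, so batch model generation continues — mirroring
  generate-many-models usage.
* Determinism: every stochastic entry point takes a seed; identical
  inputs, configuration and seed reproduce trajectories and benchmark
  tables byte-for-byte.

## Known limitations

* RMSD uses the identity atom mapping with no symmetry correction; a
  symmetric ligand docked end-for-end scores as wrong even when
  physically equivalent. The near-symmetric rod fixtures genuinely suffer
  this, which is one reason placement-only success fractions on channels
  are far below refined-pipeline recovery rates.
* The binary grid cannot rank states within its score plateaus;
  discrimination inside a pocket is entirely the refinement stage's job.
* The surrogate refinement score has no electrostatics, desolvation or
  directional terms, and the receptor is rigid; binding-affinity
  prediction is explicitly out of scope.
* Conformer generation is torsion-grid enumeration at 120°; ring
  conformations and correlated torsions are not sampled.

## A short worked example

```{r example, eval = FALSE}
cx <- make_synthetic_complex("rod_channel", n_atoms = 8, seed = 3)
res <- transform_place(cx$ligand, cx$receptor, cx$grid, cx$cfg,
                       seed = 7, native = cx$native_heavy)
res$pose$grid_score
pose_rmsd(res$pose, cx$native_heavy)
autoplot(res$trajectory)

bm <- run_benchmark(list(cx), "transform", "min",
                    n_models = 50, budgets = c(10, 25, 50), seed = 1)
tidy(bm)
autoplot(bm)
```
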