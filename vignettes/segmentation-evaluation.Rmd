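---
title: "Evaluating and ranking brain tissue segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and ranking brain tissue segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrank)
```

## The evaluation model

`segrank` scores a candidate tissue segmentation *A* against a manual
reference standard *G*, both 3D label volumes on a common registered
grid. The central assumption is that candidate and reference are
voxel-to-voxel comparable: same shape, same spacing, already aligned.
The package therefore refuses mismatched grids rather than resampling —
registration quality is an acquisition problem, not an evaluation one,
and silent resampling would blur exactly the boundary errors the
metrics are meant to expose.

The reference uses an eight-structure annotation scheme: cortical gray
matter (1), basal ganglia (2), white matter (3), white matter lesions
(4), peripheral CSF (5), lateral ventricles (6), cerebellum (7),
brainstem (8). `merge_to_tissue()` collapses 1–2 into GM, 3–4 into WM
and 5–6 into CSF. Lesions count as WM because that is what a
tissue-volume study needs; how well an algorithm actually recovers them
is measured separately by `wml_sensitivity()`, the pooled percentage of
reference lesion voxels the candidate labels WM.

Cerebellum and brainstem are excluded from evaluation. The exclusion
semantics are a design choice the annotation scheme leaves open: voxels
labelled 7/8 *in the reference* are masked out of both reference and
candidate before any metric, so a candidate is neither rewarded nor
penalised for anything it does in territory it was never asked to
segment. Candidates are expected in the merged tissue scheme (0
background, 1 GM, 2 WM, 3 CSF) — the natural output encoding for a
three-class segmenter — and raw-scheme candidates are merged
automatically.

Five components are evaluated per case: GM, WM, CSF, brain (GM + WM)
and intracranial volume (ICV = GM + WM + CSF). Brain and ICV matter for
volumetry (ICV is the standard normalisation denominator) even though
they do not enter the overall ranking.

## The three measures

**Dice overlap** `D = 2|A∩G| / (|A|+|G|) · 100` measures spatial
agreement in voxel counts (the voxel volume cancels).

**95th-percentile Hausdorff distance.** Boundary points are mask voxels
with at least one of their six face neighbours outside the mask or
outside the image; the image border counts as outside. The annotation
scheme does not dictate a connectivity, so the package fixes the most
common convention and states it — results are only reproducible if the
boundary rule is pinned down. Points live at physical voxel centres
`((i−1)dx, (j−1)dy, (k−1)dz)`, so all distances are in millimetres;
with 3 mm slices, voxel-unit distances would be wrong by more than a
factor three along z. The directed distance `h95(A,G)` is the K-th
ranked (1-based, ascending) of the minimum Euclidean distances from
each of the `N_A` boundary points of *A* to the boundary set of *G*,
with `K = ⌈0.95 N_A⌉` and no interpolation — the literal K-th order
statistic reading, with the ceiling chosen so that `K/N_A ≥ 95%`
always. An interpolated-percentile variant would differ by at most the
gap between two adjacent order statistics; the order statistic is used
because it is exactly reproducible and admits an unambiguous brute-force
oracle. The symmetric `H95 = max(h95(A,G), h95(G,A))`.

**Absolute volume difference** `AVD = |V_A − V_G| / V_G · 100` is
normalised by the reference volume and hence deliberately asymmetric.

### Numerical route for H95

Two code paths produce the same value. On point sets, minimum distances
are computed all-pairs (chunked so the cross-distance matrix stays
small). On masks sharing a grid, the package instead runs an exact
anisotropic squared Euclidean distance transform (the separable
lower-envelope-of-parabolas algorithm, implemented in C++) over the
reference boundary and samples it at the candidate's boundary voxels —
linear in grid size rather than quadratic in boundary points, which is
what makes full-volume evaluation fast. The transform is exact, not an
approximation: the test suite asserts agreement with an all-pairs
oracle to 1e-12 relative tolerance on random masks, the residual being
floating-point summation order.

### Degenerate inputs

An empty candidate component against a nonempty reference yields Dice 0
and AVD 100 by the formulas, but H95 has no boundary to measure: the
cell is recorded as `NA` and flagged `empty-candidate`. An empty
reference component leaves all three undefined (`empty-reference`).
Flagged cells are excluded from aggregation with a warning and a
reduced case count, and ranked worst-in-column rather than dropped — a
method that fails a component must not vanish from the leaderboard.

## Aggregation and ranking

Per method, each (measure, component) cell gets the arithmetic mean μ
and standard deviation σ over cases. σ is the sample standard deviation
(n−1): the test cases are a sample of the population of scans the
methods would face, and nothing downstream depends on the choice —
both conventions order methods identically when case counts are equal —
but it is fixed and documented.

Ranking: within each column, methods are ranked 1..n from the means
(Dice descending; H95 and AVD ascending). The overall score
`s = Σ r_mc` sums the nine GM/WM/CSF cells; brain and ICV columns are
computed and displayed but never scored. Final ranks sort `s`
ascending. Methods with equal `s` are separated by a σ rank: the whole
procedure rerun on the σ values, always ascending (a smaller σ means
more consistent performance, for every measure including Dice).

Two tie situations the published procedure leaves open are resolved
deterministically and flagged:

* **Within-column mean ties.** Full-precision means almost never tie,
  but rounded or degenerate inputs can. Tied methods are ordered by
  their σ in that column (ascending), then by name, and still receive
  distinct integer ranks — every column must remain a permutation for
  the score to be comparable across methods.
* **Residual ties after the σ rank** fall back to method name and are
  marked `tie_broken_by = "name"` in the leaderboard.

A consequence of ranking on full-precision means: feeding back the
*rounded, published* means of a leaderboard does not reproduce its rank
columns wherever the rounding creates ties that the original
full-precision values broke. The package therefore reproduces published
leaderboards from their printed rank cells (summing them with
`overall_score()` recovers every published score), and recomputes rank
positions only in columns whose printed means are tie-free.

## The phantom generator

`generate_phantom()` builds a raw-scheme volume from nested ellipsoids:
a peripheral-CSF shell, a cortical-GM shell, a WM core, two
lateral-ventricle ellipsoids and two basal-ganglia blobs inside the
core, randomly placed WM-lesion blobs strictly inside WM, and an
inferior hindbrain blob (disjoint from the ICV) split into cerebellum
and brainstem. The default grid is 128 × 128 × 48 voxels at
0.96 × 0.96 × 3.00 mm — the thick-slice anisotropic geometry of the
data this evaluation style targets — precisely so that any code path
that confuses voxel and physical units fails tests loudly. Default
semi-axes (52, 55, 55 mm for the ICV, 6 mm CSF and 8 mm GM shells)
give component volumes of realistic order for an adult head; the ICV
voxel volume lands within 5% of the analytic ellipsoid volume, the
discrepancy being voxelisation at 3 mm slices.

The phantom is topological, not anatomical: correct nesting, adjacency
and label inventory, no cortical folding, no partial-volume voxels, no
intensity model. That is sufficient because every quantity the package
computes is a function of label geometry alone. What passing phantom
tests do **not** show is performance on real segmentations — smooth
ellipsoid boundaries are the easy case for H95; convoluted cortex
produces far larger boundary point sets and larger percentile
distances. The phantom validates the arithmetic, not the difficulty of
the task.

Controlled corruptions with exactly known effects make the metrics'
expected values computable in closed form: `perturb_relabel()` switches
`round(f · n)` uniformly chosen voxels (so AVD = 100·f up to one-voxel
rounding), `perturb_shift()` translates all content by whole voxels (a
one-slice z-shift of an isolated voxel gives H95 = dz exactly), and
`perturb_dilate()` grows a structure by 6-connected layers (Dice
degrades and AVD grows monotonically with iterations). All randomness
is seeded and runs under a protected RNG state, so generation never
perturbs the caller's random stream.

## Testing strategy and problem sizes

Every metric is checked against an independent brute-force oracle
written in deliberately naive style: per-voxel neighbour scans for
boundaries, explicit per-point minimum-distance loops and the K-th
order statistic for H95, straight-line formula transcriptions for Dice,
AVD and the evaluation pipeline, and a from-scratch reimplementation of
the three-step σ-ranking procedure. Oracle comparisons run on random
speckle masks up to 20³ voxels (100+ pairs) and on compact phantoms
(32 × 32 × 12 and 48 × 48 × 16), while identity and invariance checks
(self-evaluation, ICV conservation under relabelling, spacing scaling,
leaderboard permutation-invariance and monotonicity) run on the
full-size default phantom. These sizes keep the whole suite under
half a minute while still exercising the anisotropic geometry; the
oracles scale quadratically, so they are the binding constraint.

## Known limitations

* No resampling or registration: volumes must already share a grid.
* Orientation matrices beyond voxel spacing are ignored; evaluation is
  defined on the common index grid.
* The conventional (maximum) Hausdorff distance and average surface
  distance are out of scope, as are sub-voxel surface meshes.
* Published leaderboards can only be reproduced to the precision they
  print: rounded means/σ do not determine the original full-precision
  rank columns (see above), and one display-only column of the bundled
  table carries a misprint in its source (a duplicated rank 12 in
  brain-AVD), preserved as printed.
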