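---
title: "Marker-based multi-view registration and phenotyping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based multi-view registration and phenotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sricp)
```

## The problem

Dense single-view reconstructions of a potted plant (e.g. from an offline
SfM-MVS pipeline fed by a stereo camera on a rotating arm) cannot capture the
whole plant: organs occlude each other, so a complete model requires merging
views taken all around the plant — here six views 60° apart. Three obstacles
stand between the per-view clouds and a usable model:

1. **Noise**: stereo matching leaves dark, drifting points along leaf edges,
   plus sparse outliers.
2. **Scale ambiguity**: every SfM reconstruction has its own arbitrary global
   scale, so the six clouds disagree in size before they can be aligned.
3. **Alignment**: marker-less registration is fragile on self-similar,
   occlusion-heavy plant geometry, so six matte calibration spheres of known
   diameter, each a distinct color, are placed on a ring around the plant and
   serve as landmarks.

`sricp` implements the full chain — color-threshold and statistical cleanup,
pot-rim scale calibration, enhanced-RANSAC sphere localization, SVD-based
self-registration (SR), ICP fine alignment, merging, and trait extraction —
plus a synthetic scene generator with complete ground truth so every stage is
testable without any real scan. All coordinates are centimetres, z-up, pot
base near z = 0.

## Preprocessing

A point is *dark* iff **all three** RGB channels fall below the threshold
(default 50). The conjunctive rule is deliberate: edge noise is black/gray
(all channels low), while marker colors are saturated — a disjunctive rule
would delete a pure red (200, 10, 10) sphere. Statistical outlier removal
uses the classic mean-distance-to-k-nearest-neighbors statistic (defaults
k = 20, cutoff at 2 global standard deviations); the method of record names
no algorithm, so the standard contract was adopted. Both filters preserve
point order and are idempotent.

## Scale calibration

The pot rim is the one structure of known physical size visible in every
view. Per view: locate the rim (modal bin of a z histogram over the
pot-colored points — an automatable stand-in for manual cropping; every z
band of the pot wall lies at the same radius, so the choice of band does not
bias the radius), slice a thin ring (half-width 0.25 cm), and fit a circle.
The fit is the algebraic Kåsa linear least-squares solution polished by
Gauss–Newton on the geometric residuals; it is exact on noiseless circles.

With fitted radii γ₀..γ₅ and reference view 2, the applied factor is
`s_i = γ_ref / γ_i`, which forces all post-scaling rim radii to equal the
reference — the testable outcome that defines the stage. The literature
ratio `μ_i = γ_i / γ_ref` is exposed as a diagnostic attribute; applying μ as
a multiplier would magnify already-large views, so the package standardizes
on the outcome-defined direction. Given the known pot diameter, a further
factor `known_radius / γ_ref` makes all views metric. The height datum is
taken separately as the 99.5th z-percentile of the pot points (the rim's top
edge): the modal-bin center is correct for slicing but sits half a band low
as a height reference.

## Enhanced RANSAC sphere localization

Each marker is segmented by nearest reference color (cap 80 RGB units), then
fit by a robustified RANSAC loop. Per iteration: sample 4 non-coplanar points
(coplanarity gate: tetrahedron volume > 1e−9 × bbox-diagonal³), solve the
exact sphere through them, and score with three enhancements over plain
RANSAC:

- **Dynamic threshold** `t = t_base · clamp(local/global, 0.5, 2)`, where
  local and global are median distances to the 10th nearest neighbor, the
  local statistic taken over points within `2 t_base` of the candidate
  surface (falling back to global when the shell is empty). The admission
  band thus widens on sparse data and tightens on dense data, and reduces to
  `t_base` (default 0.1 cm) on uniform clouds. The adaptive rule is stated
  only abstractly in the method of record; this concrete form is
  dimensionless and scale-aware.
- **Weighted scoring** `w = (|inliers|/|P|) / (μ + σ + ε)` with μ, σ the
  mean/sd of **absolute surface residuals** of the inliers and ε = 1e−12
  (weights capped at 1/ε in the noiseless limit). Residuals are absolute
  distances to the surface, not distances to the center: distances to the
  center would average ≈ r and swamp σ, while w should reward tight shells.
- **Geometric constraints on the top-K** (K = 5): when the nominal marker
  radius is known, candidates must have |r − r_nom|/r_nom ≤ 0.2 and center
  inside the sub-cloud's bounding box dilated by r_nom. The survivors are
  re-ranked by weight (resolving the ambiguity of a "best" model that fails
  the constraints: it cannot win).

The surviving model is refined by Levenberg–Marquardt on its inliers
(objective Σ(‖p−C‖−r)², analytic Jacobian, multiplicative damping), and
inliers are re-selected at the refined model; a second LM pass is available
behind a flag. The iteration count is fixed (default N = 1000, no adaptive
early exit) so a given `rng_seed` is bit-reproducible.

## Self-registration and ICP

Centers sharing a marker label in adjacent views are *homonymous points*;
at least three shared labels are required. The pairwise transform (view k+1
→ view k) is the closed-form SVD/Kabsch solution with the determinant guard
against reflections, followed by an SVD re-orthonormalization so accumulated
float error never violates the rotation invariants (checked at 1e−9).
Chaining multiplies the pairwise transforms so that the 120° view maps to
the reference through the product of the first two — five consecutive
adjacent pairs for six views (the method of record lists only five names for
its transforms; five pairs are what the chain needs).

ICP (point-to-point) then refines each coarse-aligned view. Stopping: the
stated "RMSE threshold 1e−8" with 100 iterations is interpreted as a
*change-in-RMSE* tolerance — an absolute RMSE of 1e−8 cm is unreachable on
noisy data; absolute mode remains available. An iteration that would
increase the RMSE is rejected and terminates the loop, making the reported
RMSE sequence non-increasing by construction. The default correspondence
gate is 5× the target's median point spacing; the pipeline additionally
enables an adaptive rejection (drop correspondences beyond 3× the current
median correspondence distance, re-evaluated each iteration). The adaptive
rule matters because the SR initialization is already accurate to the
marker-fit scale (≈0.01 cm here), while adjacent views overlap only
partially: with a wide gate, one-sided nearest-neighbor pulls from
non-overlapping surface parts (e.g. opposite sphere hemispheres) bias ICP
*away* from the truth. By default each view is refined against the
accumulated reference (view 0 plus previously aligned views), which reduces
drift for the 180°–300° views; pure view-0 targeting is selectable.

## Traits

- **Plant height**: max z minus the pot-rim datum.
- **Crown width**: diameter of the XY projection — the maximum pairwise
  horizontal distance, computed on the convex hull (identical to the O(N²)
  maximum; a bounding-extent average is available by option). The method of
  record does not define crown width; the hull diameter is the conservative,
  orientation-free choice.
- **Leaf length/width**: principal axes of the leaf's coordinate covariance,
  ordered by explained variance; each trait is the euclidean distance
  between the two *actual cloud points* with extreme projections on that
  axis, so the measurement is literally a linear distance between two
  points. For a curved leaf this chord provably underestimates the arc
  length — the package reproduces that bias deliberately, since it explains
  why curved-leaf species measure worse than flat-leaf species under
  chord-based estimation. Leaf segmentation is an input (labels), never a
  computation: leaf selection is manual in the emulated workflow.

## The synthetic world

The generator states the world the tests live in; its defaults were chosen
once, as follows, and are not tuned against test outcomes:

- Pot radius 8 cm, rim at z = 12 cm; marker radius 2 cm on a 22 cm ring —
  the scale of a small potted seedling with commercial calibration spheres.
- Plant: 30 cm stem bearing four elliptical leaves (8 × 3.5 → 6 × 2.5 cm,
  two flat, two bent with curvature 0.06–0.08 cm⁻¹, matching the flat- vs
  curved-leaf contrast the trait analysis needs).
- Six views 60° apart; per-view scale drift uniform in [0.9, 1.1] (SfM scale
  ambiguity); surface noise σ = 0.05 cm; 2% uniform outliers; dark edge
  points at 5% of each leaf's samples (RGB < 50, exercising the color
  filter).
- Densities (≈10⁴ world points) give a realistic ~0.2–0.4 cm point spacing
  while keeping the full suite inside its runtime budget.
- Visibility culling keeps points whose outward normal faces the camera
  (direction +y, tilted 22° downward so the rim stays visible); leaves are
  thin and kept from both sides. This produces the partial, roughly
  hemispheric marker coverage that motivates the robust sphere fit. The
  generator does **not** simulate occlusion between objects, perspective
  effects, stereo-matching texture failures, or wind — a green suite
  establishes correctness of the geometry pipeline under its stated noise
  model, not performance on real scans.

Views are produced by transforming the world (equivalent to a rotating
arm), so true pairwise transforms are exactly 60° z-rotations unless a
transform jitter is enabled; the ground truth records transforms, scales,
sphere centers, per-view visibility, and trait values (for curved leaves:
both the tip-to-tip chord, `2 sin(κL/2)/κ`, and the arc length L).

## Numerical choices and degenerate inputs

- Rotation validity gates at 1e−9 (orthonormality and det = +1); every
  transform constructor enforces them, so reflections cannot enter a chain.
- Collinearity gates: circle fit (rank of centered coordinates), SVD
  transform (second singular value ≤ 1e−9 × first), leaf axes (second
  eigenvalue ≤ 1e−12 × first). All raise classed errors naming the
  constraint.
- The outlier filter admits points up to a 1e−12 relative tolerance above
  the cutoff so perfectly homogeneous clouds survive float jitter.
- PLY I/O supports ASCII and binary-little-endian; ASCII (default on write)
  prints coordinates at %.9g, sufficient for exact float32 round-trips.
  Labels persist as an `int label` vertex property readable by generic
  viewers.
- Nearest-neighbor queries are exact brute-force C++ kernels; clouds at the
  package's working sizes (≤ ~5 × 10⁴ points) never need a spatial index,
  and ICP subsamples the source (default 2000 points) for correspondence
  search only.

## Known limitations

- Extreme-value statistics (max z, max pairwise distance, extreme
  projections) inherit a positive bias of order σ from surface noise; at
  σ = 0.05 cm this approaches the 3σ tolerance for the crown of the merged
  six-view model (six noisy copies of each leaf tip), which is why trait
  recovery is validated on a single noisy sampling of the plant while the
  merged model is validated by cloud-to-cloud distance.
- Leaf **width** is the most bias-prone trait: the minor-axis extent of an
  elongated leaf selects its endpoints from a wide, shallow boundary region,
  so max-selection under noise overshoots by ~2–3σ in median (and the
  endpoints' offset along the major axis adds a second-order term
  ≈ a²σ/(W b) for semi-axes a ≥ b). Length, whose tips are sharply sampled,
  recovers within 3σ. Both effects are properties of the "linear distance
  between two extreme points" estimator itself, not of the registration.
- The scale stage assumes the pot rim is circular and horizontal; tilted
  pots would need ellipse fitting (out of scope).
- Marker-less registration, automatic leaf segmentation, and mesh-based
  leaf area are out of scope by design.
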