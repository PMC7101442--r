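---
title: "Orientation tensor fields from segmented microscopy volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation tensor fields from segmented microscopy volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtract)
```

## The method in one paragraph

A segmented 3D volume — a binary vascular mask or a labelled cell
population — is reduced to a set of oriented *feature descriptors*: for
vessels, the chord between two adjacent nodes of the medial-axis skeleton
graph; for cells, the principal axis of the best-fitting ellipsoid. A
cubic window slides across the volume; the descriptors whose midpoints it
contains contribute their endpoint pairs ±**r**/2, and the covariance of
that pooled, zero-mean endpoint cloud is the window's 3×3 orientation
tensor. The tensor's eigen-system summarizes the local architecture: the
principal eigenvector is the prevailing orientation, the eigenvalue
spread its anisotropy. Scalar and color maps, wall-frame angle analyses
and deterministic streamline tracking are all derived from this eigen
field. Because the descriptors and window size are user choices, the same
machinery describes a capillary bed at the 90 µm mesoscale or a
macrophage population at any other scale.

## Assumptions

* **Segmentation is given.** Everything downstream consumes a mask or
  label volume; `binarize_baseline()` (threshold + small-component
  removal) exists only as a simple reference path, and the Dice
  coefficient quantifies agreement between any two masks. The framework
  is independent of how segmentation was produced.
* **Descriptors are axial.** A vessel chord and a cell axis carry no
  intrinsic sign; all statistics (covariance, DEC, helix angles) and the
  tracker treat **v** and −**v** identically. This motivates the ±**v**/2
  endpoint construction, whose pooled mean is exactly zero by symmetry.
* **Straight-chord approximation.** A vascular descriptor is the chord
  between adjacent graph nodes, not the curved slab path. On tortuous
  vessels the chord underestimates length and smooths direction;
  `segments_from_graph(subdivide_um =)` optionally splits long edges at
  their voxel path to bound the chord error (off by default).
* **Population covariance.** The window tensor divides by 2N, treating
  the endpoint cloud as the full population with known zero mean; the
  (2N−1) sample variant is available via `sample_covariance = TRUE` and
  differs negligibly at the default counts.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` (W) | 90 | µm | edge of the cubic pooling window; sets the scale of the representation. Larger windows smooth the field |
| `stride` | 20 | µm | spacing of window centres; windows overlap when stride < W |
| `min_count` | 2 | descriptors | windows with fewer descriptors are invalid: one segment gives a rank-1 tensor with no dispersion meaning, and counts weight statistical significance |
| `step` | stride/2 | µm | RK2 integration step; half the grid spacing is stable for the midpoint scheme |
| `max_angle` | 35 | degrees | single termination criterion — larger than myofiber curvature per voxel, needed to follow a branching vascular continuum. No FA threshold is used |
| `fraction` | 0.15 | — | display subsampling of dense all-voxel tractograms |
| `prune_below` | 0 (off) | µm | removal of short terminal skeleton branches; off by default because any pruning rule is a modelling choice |
| `degenerate_tol` | 0.05 | — | cells with (λ₁−λ₂)/λ₁ below this have no meaningful axis (spheres) and are excluded from orientation statistics |

Window membership is decided by the descriptor *midpoint* alone, with the
window half-open on its high side: every midpoint belongs to exactly one
window per stride cell at equal window and stride, and a segment spanning
a boundary is never double counted.

## Skeletonization and graph extraction

Thinning is a Lee-style iterative erosion implemented in C++: six
directional subiterations per pass delete border voxels that are *simple*
for the (26, 6) connectivity pair — the object voxels of the 3³
neighbourhood form one 26-connected component and the face-adjacent
background forms one 6-connected component — while end points (exactly
one neighbour) are preserved and candidates are re-checked sequentially at
deletion time. This guarantees the skeleton has the same number of
26-connected components as the mask. Skeleton voxels are then classified
by neighbour count (end point < 2, slab = 2, junction > 2); mutually
adjacent end-point/junction voxels merge into one node at their centroid
(thinning routinely leaves junction clumps at bifurcations), slab chains
become edges, and edge length is the sum of inter-voxel distances in
physical µm along the path, honouring anisotropic spacing.

Two practical notes. First, directional thinning is order-dependent:
permuting the grid axes can move the centreline by a voxel or two, so
topology is exactly permutation-invariant but total edge length only to a
few percent — the tests assert exactly that. Second, oblique tubes
rasterize with staircased surfaces that can leave 1–3-voxel spurs at
junctions; `prune_below` removes such terminal branches and dissolves the
degree-2 nodes this leaves behind, merging their incident edges. With
noise-free tube phantoms of radius 3 voxels and branches at 0°/45°/90°,
skeletonize + build_graph recovers end-point, junction and edge counts
exactly and edge lengths within ten percent (within ~6 % in practice).

## The wall frame and transmural analysis

The anatomical wall frame is idealized as a cylinder around a
user-supplied long axis: radial r̂ outward from the axis, longitudinal l̂
along it, circumferential ĉ = l̂ × r̂, and transmural depth d linear in
radius from 0 at the epicardial to 1 at the endocardial radius. The helix
angle is the signed angle of **v**₁'s tangent-plane projection against ĉ,
positive toward +l̂, in (−90°, 90°]; the transverse angle is the signed
elevation toward r̂. Both are axial (±**v**₁ agree); a purely radial
eigenvector has undefined HA (NaN) and TA ±90°. Bin means use circular
statistics on doubled angles (180°-periodic data), and the transmural
span HA(0) − HA(1) comes from an M-estimator linear fit (`MASS::rlm`,
least-squares fallback) over all valid centres, robust to the mixed-voxel
outliers near boundaries.

A window of edge W straddling the wall boundary pools descriptors from a
depth range of W/(epi−endo); such windows blur the profile. The
`margin` argument of `build_wall_frame()` therefore restricts validity to
centres at least a chosen distance (typically W/2) inside the wall.
Arbitrary anatomical meshes are out of scope; the cylinder is an explicit
modelling assumption.

## Tractography

Tracking is deterministic RK2: at position x with heading h, v_a =
dir(x) sign-aligned to h; v_b = dir(x + (step/2)·v_a) sign-aligned to
v_a; the track stops if the angle between h and v_b exceeds `max_angle`,
else advances by step·v_b. Each seed is tracked bidirectionally (the
field is axial) and the halves are concatenated; the finished polyline is
oriented canonically (lexicographically smallest endpoint first) so that
a global eigenvector sign flip changes nothing, byte for byte.
Termination reasons — `angle`, `boundary`, `invalid_voxel`, `max_length` —
are recorded per track end. "All voxels" seeding means all valid tensor
centres; `seed_stride` decimates seeds for speed.

Direction lookup is nearest-valid-centre by default — the simplest
faithful reading of voxel-wise tracking — with trilinear interpolation
(per-corner sign correction, invalid corners dropped) behind a flag.
Tracking operates in eigenvector space; interpolating in tensor space and
re-decomposing would be a possible extension. For geometric verification
of the integrator itself, `track()` also accepts an analytic direction
function: on a circular field of radius 50 µm at step 0.5 µm the radial
drift after a revolution is below 10⁻⁴ % of the radius, far inside the
second-order error budget — a grid-sampled field would confound that
measurement with direction-quantization error of the lookup, which is a
property of the representation, not the scheme.

## Phantoms: what they emulate, and what not

The generators provide the ground truth the real study material cannot:

* `helical_shell_spec()` — a cylindrical wall of vessel segments whose
  helix angle follows a prescribed law across the wall (default linear
  +60° → −60°, the classic transmural rotation). Defaults place a
  400 µm-thick wall at radii 300–700 µm — murine-ventricle scale, and
  several windows thick so that the 90 µm window's transmural footprint
  (0.225 in depth) stays small — with ~14 segments per window (density
  2 × 10⁻⁵ µm⁻³), segment length 15 µm and Gaussian angular jitter.
* `cell_population_spec()` — non-overlapping solid ellipsoids (rejection
  sampling keeps per-cell moment ground truth exact) with axial
  Watson-distributed long axes about a mean direction; concentration κ
  spans isotropic (0) to tightly aligned.
* `rasterize_tubes()` closes the loop for end-to-end tests: segments →
  mask → skeleton → graph → descriptors should reproduce the input.

Fixed seeds give byte-identical phantoms. What the phantoms deliberately
do *not* model: the imaging chain (PSF blur, shot noise, attenuation with
depth), segmentation errors other than additive Gaussian intensity noise,
vessel radius variation and curvature within a segment, and contacting
cells. Passing tests therefore demonstrate correctness of the
skeleton-to-tensor-to-tractogram machinery under known geometry, not
robustness to real acquisition artifacts.

## Numerical choices

* Eigen-decomposition uses the symmetric solver; eigenvalues in
  [−10⁻⁹, 0) are clamped to zero (roundoff from the PSD construction),
  and each eigenvector's largest-magnitude component is made nonnegative.
  Under exact ties the solver's deterministic output plus this sign rule
  fix the result; tests never assert eigenvector identity at ties.
* FA uses the standard √(3/2)·√Σ(λᵢ−λ̄)² / √Σλᵢ² form; the Westin indices
  use the sum-normalized convention cl = (λ₁−λ₂)/Σλ, cp = 2(λ₂−λ₃)/Σλ,
  cs = 3λ₃/Σλ, chosen because the three indices then partition unity — a
  sharply testable property; the λ₁-normalized variant is a flag away.
* The tensor accumulation sums **v****v**ᵀ/(4N) per window; agreement with the
  naive two-point-per-descriptor double loop is at machine-rounding level
  (≤ 10⁻¹² per entry on hundreds of random sets).
* Degenerate inputs: empty descriptor sets give all-invalid fields, not
  errors; zero-length chords are dropped and counted; an all-zero
  eigenvalue triple has undefined FA/Westin (NaN); slab-only skeleton
  cycles get one promoted node and a self-loop so every slab voxel
  belongs to exactly one edge.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
phantom shells of 3–5 × 10³ segments on ~50 000-window grids, tube
phantoms up to 100 × 100 × 24 voxels, 50-cell label volumes at 220³ µm,
100 random descriptor sets of up to 500 descriptors for the covariance
oracle, and a full two-run pipeline determinism check — a few minutes in
total on one core. All sizes are set in the test and script sources and
scale linearly if larger checks are wanted.

## Known limitations

* The cylindrical wall frame cannot follow a real ventricle's taper or
  apex; transmural profiles from real hearts need an anatomical frame.
* Chord descriptors underestimate the orientation dispersion of highly
  tortuous vessels unless subdivision is enabled.
* Directional thinning is axis-order dependent at the voxel level (see
  above); centreline positions are accurate to ~1 voxel, not exact.
* PNG map export is 8-bit with a text sidecar recording the scale;
  quantitative consumers should use the TIFF/NRRD outputs instead.
* Tracking in eigenvector space with nearest-centre lookup quantizes
  direction at the stride scale; trilinear interpolation softens but does
  not remove this.
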