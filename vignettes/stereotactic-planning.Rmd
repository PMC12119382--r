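---
title: "Frame-based stereotactic planning: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-based stereotactic planning: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoframe)
```

## The problem

A stereotactic head frame rigidly fixes a Cartesian coordinate system to the
skull. Surgery is planned by reading off the target's frame coordinates and
two angles — arc and ring — that orient the semi-circular guide arc. The
computational task is to recover the frame's pose from a CT of the head
wearing the frame, so that any image point can be expressed in frame
coordinates. The frame makes this possible by carrying two lateral N-shaped
localizer plates (two vertical rods and one diagonal each) that are bright
in CT.

## Coordinate systems

Images live in RAS millimetres (axes toward the patient's right, anterior,
superior; DICOM's LPS convention is converted on load by negating the first
two world axes). The frame coordinate system has its origin at the superior
posterior right corner, so coordinates are positive over the head, with the
centre at (100, 100, 100) mm for the standard frame. Its X axis is
anti-parallel to R, Y parallel to A, Z anti-parallel to S. With the
registered frame centre at the RAS origin,

$$ (X, Y, Z) = (c_x - R,\; c_y + A,\; c_z - S), $$

with $c = (100, 100, 100)$ by default. `frame_spec()` exposes the plate
separation (190 mm), plate width and height (120 mm each) and the centre as
parameters so that non-standard frames can be described; the four reference
vertices — the *tops* of the vertical rods, where upward tracking
terminates — derive from these values. The conversion and its inverse are
exact; a property test checks the round trip on random points.

## Fiducial detection (layerwise max-intensity tracking)

The user supplies four rough seeds on any axial slice, in any order. Each
seed is refined to the brightest voxel in the in-plane square window of
Chebyshev radius 10 voxels (a 21 × 21 region) on its slice, then tracked
upward: at each next slice toward the superior direction the same window,
re-centred on the previous position, is searched for its maximum; tracking
stops when that maximum falls below 500 HU or the volume ends. The last
accepted voxel is the rod vertex.

Choices worth stating explicitly:

* **Window radius, not diameter.** The 10-pixel neighbourhood is
  interpreted as a radius. At 1 mm spacing the window then spans 21 mm,
  large enough to absorb realistic mis-clicks yet far smaller than the
  ~60 mm gap to the diagonal rod at mid-frame, so the walk cannot hop rods.
  Both radius and threshold are configurable.
* **Re-centred, constrained search.** Each slice's search window is centred
  on the previous slice's maximum rather than on the original seed (the rod
  drifts in-plane when the frame is tilted) and is never global (a global
  slice argmax could jump to another rod).
* **Superior from the affine.** "Upward" is derived from the volume affine,
  not from slice ordering, so head-first and feet-first acquisitions track
  identically.
* **Determinism.** Ties in the window argmax are broken toward the smallest
  (i, then j) index. Identical volume and seeds give bit-identical output.
* **Whole voxels.** Vertices are voxel centres; no sub-voxel centroid
  refinement is attempted. Vertex accuracy is therefore bounded by the
  voxel quantization (about half a voxel per axis).

Labels are assigned by quadrant relative to the four-vertex centroid in
RAS (left/right by R, anterior/posterior by A). Any vertex within 1 mm of a
centroid axis, duplicate vertices, or two vertices in one quadrant raise an
error asking for re-seeding rather than guessing. A seed on the diagonal
rod is not rejected outright — no reliable local criterion exists — but
surfaces through these checks or through the registration RMSE.

## Frame registration

The four labelled vertices are aligned to their reference positions by the
Kabsch algorithm: subtract centroids, SVD the cross-covariance, and correct
the sign of the smallest singular direction so the rotation has determinant
+1 — the solver never returns a reflection, even for degenerate or mirrored
input. Correspondence comes from the labels; with four known-geometry
points there is nothing to assign. No scale or shear is estimated: the
frame is rigid.

The fiducial registration error is reported as the RMSE of the four
per-fiducial residual distances after the optimal alignment. The warning
threshold defaults to 1 mm — the level at which re-seeding is advisable —
and is a `frame_spec` parameter. Collinear point sets are rejected (the
rotation about the line is undetermined); the check is on the second
singular value of the centred source set.

## Trajectory planning

Both target and entry are mapped through the registration transform first;
angles are then computed from the registered RAS components:

$$ \mathrm{arc} = \left|\cos^{-1}\frac{E_r - T_r}{\lVert E - T\rVert}\right|,
\qquad
\mathrm{ring} = 90^\circ - \operatorname{atan2}(E_a - T_a,\; E_s - T_s), $$

with ring wrapped into [0°, 180°). The two-argument arctangent is used
because the single-argument form is undefined at $E_s = T_s$ and
quadrant-ambiguous for $E_s < T_s$; on the half-plane $E_s - T_s > 0$ the
two coincide (verified to 10⁻⁹ degrees on 10⁴ random pairs). The arc angle
is measured against the R axis exactly as conventionally printed, although
the frame X axis is anti-parallel to R; physical frames whose engraved
scales differ can be accommodated by optional per-angle offsets (default
0°). Coordinates are displayed to 0.1 mm and angles to 0.1°, matching
frame vernier resolution; full precision is kept internally.

## The phantom generator

`generate_phantom()` builds the validation world: an air background
(−1000 HU), a head ellipsoid (semi-axes 70 × 85 × 75 mm of 40 HU tissue
with a 5 mm, 1000 HU skull shell), and the six localizer rods rasterized as
1.5 mm-radius cylinders of 2500 HU at a known rigid pose, on a 256 × 256 ×
200 grid of 1 mm voxels by default. Ground truth (posed vertices, the pose,
the grid geometry) is returned with the volume. A spherical target marker
(5 mm diameter, 1200 HU) can be embedded to mark a target unambiguously,
and `perturb_seeds()` generates reproducible sets of deliberately
mis-placed seeds for seed-sensitivity experiments.

Numerical choices:

* **Rasterization** is a voxel-centre-in-solid test, so noiseless phantoms
  are bit-reproducible. Its side effect is that a rod cross-section is a
  plateau of identical values: under the deterministic tie rule a perfectly
  axis-aligned rod resolves to the corner of its cross-section, and under
  noise the plateau argmax is uniform over the cross-section. Real CT rods
  instead show a partial-volume peak near the axis. The generator therefore
  offers `smooth_fwhm_mm` (separable Gaussian, exact and deterministic) as
  a partial-volume acquisition model; 2 mm FWHM gives rod profiles peaked
  at the axis. Accuracy experiments use the smoothed phantom; determinism
  and seed-identity experiments use the sharp default.
* **Default rod HU (2500)** sits safely above the 500 HU termination
  threshold, and the background safely below, so tracking terminates at rod
  tops (±1 slice).
* **Field of view.** The pose must keep all rod endpoints inside the grid;
  a rod surface merely grazing the boundary is clipped by the rasterizer.
  The default grid holds poses up to roughly 10–15° and 15 mm of
  translation; batch experiments that draw poses up to ±15° and ±20 mm use
  a 300 × 300 × 260 grid at the same 1 mm spacing.
* **Noise** is additive Gaussian, seeded and restorable (`rng_seed`), 0 by
  default; 30 HU is used as the realistic level in validation batches.

What the phantom does *not* model: anatomy, beam hardening and metal
artifacts, helical reconstruction, gantry tilt, and non-axial slice
orientations. Passing phantom suites therefore demonstrates the geometric
correctness and noise robustness of the chain, not artifact robustness on
clinical data.

## Validation experiments and problem sizes

The test suite runs, among others: pose recovery on random rigid poses of
the reference vertices (rotations to ±30°, translations to ±50 mm,
recovered to 10⁻⁹); a reflection-guard check against a 2° brute-force
rotation grid; seed-insensitivity with five seed sets displaced up to 7
voxels (identical vertices on the noiseless phantom, within one voxel at
30 HU noise); and an end-to-end batch of 20 phantoms at random poses within
±15° / ±20 mm with 30 HU noise and the partial-volume model, requiring
registration RMSE below 1 mm in at least 19 of 20 runs and a mean planned
target error within 1 mm of ground truth. These sizes keep the full suite
around four minutes on a single core while leaving each statistic
well-resolved.

## Agreement statistics

`point_agreement()`, `angle_agreement()` and `bland_altman()` implement the
comparison toolkit for two case-paired plan sets: per-case Euclidean
distances, per-axis absolute and signed deviations with paired t-tests,
means ± SD with t-based 95 % CIs, and Bland–Altman bias with 95 % limits of
agreement (bias ± 1.96 SD). Differences are always A − B and SDs use the
n − 1 denominator; both conventions are recorded in the JSON output since
either choice is defensible and published analyses do not always state
theirs.

## Known limitations

* DICOM support is deliberately minimal: uncompressed little-endian
  single-frame CT slices forming one series, which covers scanner exports
  of this kind and the package's own writer; compressed or multi-frame
  series should be converted to NIfTI first.
* MRI localizers, gantry-tilt correction and deformable registration are
  out of scope; the registration is rigid by construction.
* Seed-free automatic detection is not attempted: the four seeds are the
  user's statement of *which* bright structures are the verticals, and the
  intensity tracking removes the precision burden from that statement.
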