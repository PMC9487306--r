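---
title: "Sub-arc collimator angle optimization: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-arc collimator angle optimization: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what is modeled, the
choices made where the design was genuinely open, and what the tests do and
do not establish.

## The problem

Single-isocenter coplanar VMAT for multiple brain metastases treats 2–5
separated targets through one rotation axis. In the beam's eye view (BEV)
the target silhouettes orbit each other with gantry angle; whenever two
silhouettes share an MLC leaf pair, the pair is a single interval and must
open across the gap between them (*island blocking*), exposing normal
brain. Rotating the collimator re-assigns silhouettes to leaf pairs, but
the best angle changes along the arc. The package segments each arc into a
few sub-arcs and selects one collimator angle per sub-arc.

## Geometry model

* **Coordinates.** Patient DICOM LPS, millimetres; gantry per IEC 61217
  (0° = source anterior, 90° = source at patient left). The BEV frame is
  attached to the gantry head: `u` is the leaf-travel direction at
  collimator 0°, `v` the leaf-stacking direction (the patient
  superior–inferior axis for a coplanar arc). The collimator angle θ is
  the machine angle; fitting happens in the frame rotated by −θ.
  A consequence worth knowing: in parallel-projection mode, opposed beams
  give exactly θ-mirrored (not identical) heatmap rows,
  `row(g+180°)(θ) = row(g)(−θ mod 180°)` — the two beams reach the same
  physical apertures at mirrored machine angles. A test asserts this
  mirror at machine precision.
* **Projection.** Divergent by default: a point at distance `d` from the
  isocenter plane toward the source magnifies by `SAD/(SAD − d)`,
  SAD = 1000 mm. Parallel mode (`mode = "parallel"`) is available as the
  analytic limit used by several symmetry tests.
* **Structures.** Planar contour stacks (CT-like, 1 mm slices by default).
  Two projection routes exist:
  * *contour route* (used by `mci_heatmap()` for contour input): each
    slice polygon is projected directly; between adjacent slices the
    contour is interpolated vertex-wise and the end slices are extruded
    half a spacing. Because every beam is coplanar, a filled slice casts a
    shadow that is exactly one `u`-interval per raster row, so the
    silhouette is assembled analytically with no voxel-lattice artifacts.
  * *voxel route* (`rasterize_structure()` + `project_bev()`): even-odd
    rasterization at 1 mm, sub-voxel supersampling, point projection,
    morphological closing. This is the generic route for mask input and
    the slower reference in cross-checks.
* **Aperture fitting.** The leaf bank is a symmetric Millennium-120-class
  model (10 × 10 mm, 40 × 5 mm, 10 × 10 mm per side; bank centered on the
  isocenter projection). For each pair whose band contains silhouette, the
  tips go to the outermost extent, snapped outward (never clipping
  target), so MCI ≤ 1 is an invariant. Disconnected blobs in one band
  produce one spanning opening — this is what makes island blocking
  visible to the score. Aperture area counts open-pair rectangles only; a
  jaw rectangle bounds them for the field size.

## The MCI heatmap and its numerics

`MCI = A_TP / A_MLC` is evaluated on a grid of 180 control points
(2°/CP over a 358° arc, endpoints 179°→181° inclusive) × 180 collimator
angles (1° steps; 180° is redundant with 0° for a symmetric bank). The
silhouette area `A_TP` is rotation-invariant and computed once per control
point; per angle only the silhouette's boundary is rotated and reduced to
per-band extents.

Two deliberate numerical choices:

* **Half-pixel corner inflation.** Extents are inflated by the corner
  support of a half-pixel square, `px/2·(|cos θ| + |sin θ|)` per side.
  This models conformal fitting on the rasterized BEV (it equals the
  snap-outward rule of `fit_aperture()` for unrotated masks) and it is
  what breaks a genuine degeneracy: for ideal disks, every collimator
  angle that separates the targets scores within ~0.005 of every other,
  so the argmax would otherwise be decided by noise. With the inflation,
  the angle that aligns the separation with the leaf-stacking direction
  wins systematically; for two 10 mm-radius spheres separated 60 mm along
  the patient axis, the per-CP argmax is exactly the predicted angle at
  every control point. For *tightly* separated small targets slight tilts
  can genuinely score higher; the ±10° alignment rule should be read as a
  property of well-separated targets.
* **Resolution and symmetry checks.** Defaults are 1 mm slices and 0.5 mm
  BEV pixels: adequate for cm-scale lesions at interactive cost (a full
  180 × 180 heatmap builds in a few seconds). Two fixture artifacts matter
  when *verifying rotational symmetry* with spheres: a 1 mm-sliced stack
  has flat polar caps that are genuinely anisotropic under rotation, and
  rim-band chords are sensitive to raster phase. The symmetry suite
  therefore runs at 0.25 mm slices and pixels, where both artifacts sit
  below the 0.02 flatness band; this isolates algorithmic anisotropy from
  properties of coarse fixtures, and the defaults are unchanged for real
  use.

The boundary-point fast path and the explicit `rotate_bev()` +
`fit_aperture()` route agree within raster resampling tolerance (< 0.08 in
MCI); a seeded regression test pins this.

## Sub-arc segmentation

The published rule — avoid the worst MCI, sub-arcs over 30°, fewer than
10 — is a goal, not an algorithm. It is implemented as an exact
optimization: maximize the sum over segments of the best summed MCI
(`max_θ Σ_cp MCI`), by dynamic programming over segment endpoints, subject
to span ≥ 30° and ≤ 9 sub-arcs. Segments forced across low-MCI regions
score poorly at every θ, so "avoiding the worst MCI" is subsumed. Because
the objective never decreases under splitting, the unconstrained optimum
always uses the maximum count; among partitions within a relative `delta`
(default 0.01) of the best score the fewest-sub-arc one is returned, which
reproduces clinically small counts without a hand-tuned penalty.

Conventions: sub-arc spans are measured between gantry boundary values, so
they sum to 358° and the terminal segment needs one extra control point;
"more than 30°" is read as ≥ 30° and "less than 10" as ≤ 9; θ ties break
toward the lowest angle; equal-score partitions break toward the
lexicographically smallest boundary sequence. A brute-force enumerator
with identical conventions serves as the oracle (`brute_force_segment()`,
guarded to ≤ 40 control points); DP and brute force agree bit-for-bit on
seeded random instances. Infeasible constraints (minimum span exceeding
the arc) error before any computation.

## Dose metrics

`D_x%` uses linear interpolation on the sorted voxel-center sample
(`stats::quantile` type 7); `V_t` counts voxel centers at dose ≥ t, with no
sub-voxel partial volumes. CI is the plain prescription-isodose-to-target
ratio (not the Paddick variant), counted inside a body structure when one
is supplied, else over the whole grid. When a dose grid is finer than the
contour stack, grid slices map to the nearest contour within half the
coarser spacing. Reported cohort medians use midpoint-of-two for even n
and round half away from zero to one decimal — the convention that
reproduces the bundled cohort's printed statistics.

## The phantom generator

`phantom_case()` emulates the study conditions: 2–5 lesions, volumes
uniform in 2.2–18 cc (the bundled cohort's per-lesion range), placed
uniformly in a 90 mm head shell with an 8 mm skull margin and ≥ 20 mm
surface gap by rejection sampling; spheres by default, ellipsoids (volume-
preserving random axis ratios 0.7–1.3) for staircase-sensitive tests.
Rasterized lesion volumes land within 2% of the request for radii ≥ 5 mm.
All randomness flows through `seed`.
`make_synthetic_dose()` is a radiosurgery-shaped substrate, not a dose
calculation: prescription dose inside each lesion, Gaussian falloff with
distance to the lesion surface (σ = 5 mm default), voxel-wise maximum
where lesions interact. Its virtue is closed-form verifiability — e.g.
`GI = (1 + (σ/R)√(2 ln 2))³` for a sphere — which the tests exploit.

What the phantoms do **not** emulate: irregular lesion shapes, organs at
risk, CT appearance, couch/non-coplanar geometry, and, most importantly,
an optimizer's dose: passing tests show the geometry/optimization chain is
correct, not that any clinical dosimetric gain would be realized, which
requires a treatment planning system.

## Inter-lesion distance convention

The per-axis maximum distance (R_max) is the distance between the
outermost bounding-box extremes over all lesion pairs, per axis. The
bundled cohort table ships transcribed values; one of its rows prints a
total volume consistent with its per-lesion volumes only under an obvious
one-character correction, which the table adopts (19.3 cc).

## Problem sizes in the test suite

Unit tests use reduced grids (e.g. 45 × 45 heatmaps on a 352° arc at
8°/CP, 20–40-CP random instances for the DP oracle); the end-to-end test
and `scripts/acceptance.R` run the full dual-arc 180 × 180 condition. The
bulk MCI-validity sweep uses 100 seeded phantoms with spot-checked control
points rather than full heatmaps.

## Known limitations

* Deliverability is not modeled: no leaf-speed, interdigitation,
  tongue-and-groove, transmission or MU computation.
* The two arcs of a dual-arc plan are optimized independently.
* Contour interpolation between slices assumes slice polygons with equal
  vertex counts (true for generated phantoms); other stacks fall back to
  slab extrusion.
* DICOM I/O is not included; structures travel through a documented JSON
  contour format, doses as in-memory grids.
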