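---
title: "A static string-on-pulley model of middle-deltoid coaptation after reverse shoulder arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A static string-on-pulley model of middle-deltoid coaptation after reverse shoulder arthroplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaptR)
```

## The model

After reverse shoulder arthroplasty (RSA) the glenosphere — the ball,
now fixed on the scapular side — sits under the middle deltoid (MD).
The MD wraps it like an inextensible string on a pulley: each fiber
runs from a proximal insertion point (PIP) on the acromion, over the
implant surface, down to the distal insertion point (DIP) at the
deltoid V on the humerus. In a plane slice through the wrap this gives
three measurable angles:

* **E** — between the *MD line* (the tangent from the DIP to the
  in-plane implant circle) and the humeral diaphysis axis Y'Y;
* **B** — the fiber's change of direction at the pulley, i.e. the angle
  between the two fiber directions taken towards the pulley (DIP →
  pulley and PIP → pulley);
* **T = B/2** — because the two tangent lines from their intersection
  point are symmetric about the line to the circle centre, T is the
  tangent half-angle `asin(rho / L)`.

With equal fiber tension `F1 = F2` (the string assumption) and static
equilibrium `F1 + F2 + R = 0`, the axial components are

```
Ry   = F1 cos(E) + F1 cos(2T + E) = 2 F1 cos(T) cos(T + E)
R'y  = -2 F1 cos(T) cos(T + E)        (action of the MD on the pulley)
F'1y = F1 cos(E)                      (elevating action at the DIP)
```

and the **coaptation/elevation ratio** is

```
CER = | R'y / F'1y | = | -2 cos(T) cos(T + E) / cos(E) |.
```

A CER near 0 means the MD mostly elevates (destabilises) the joint; a
CER near 1 means the head-centering (coapting) component is as large
as the elevating one. The two printed forms of `Ry` are a
product-to-sum identity; `force_components()` verifies the vector
equilibrium to 1e-9 and the test suite checks the identity on a random
angle grid.

The model is static (one arm position, nominally 80° between diaphysis
and scapula), planar (each slice analysed independently) and massless
(fiber mass, thickness and all other muscles are ignored). Those are
assumptions of the measurement protocol itself, not simplifications we
added.

## The measurement pipeline

1. **ILSS fit** (`iterate_fit()`): the implant cannot be segmented
   directly (metal artifact), so a sphere — the Implant Least-Squares
   Sphere — is fitted to points picked on the internal aspect of the
   MD. The automated loop reproduces the interactive protocol: fit
   (linearised algebraic least squares on
   `sum((||p-c||^2 - r^2)^2)`), eliminate points whose surface normal
   disagrees with the sphere normal (scalar-product rule), prune the
   10 % of points with largest `dist^2 = | ||p-c||^2 - r^2 |`, refit;
   stop when the radius moves by < 0.05 mm or after 5 iterations, then
   polish with a Gauss–Newton pass on the geometric loss
   `sum((||p-c|| - r)^2)`. An acromial reference sphere is fitted the
   same way (pruning optional) to provide landmark Point 1.
2. **Slice planes** (`plane_from_three_points()`): each of the four
   anatomical slices S1–S4 is the plane through Point 1 (acromial
   sphere centre), Point 2 (one of the Sakoma insertion sites P1, M1,
   A3, A2 walked in 10° steps along the acromion) and Point 3 (centre
   of the humeral diaphysis). The in-plane y axis is the projected
   diaphysis direction; x is oriented lateral-positive.
3. **Resampling** (`resample()`): label volumes are resampled into the
   plane with the kernel `w(t) = 2t^3 - 3t^2 + 1` over the 8 corner
   voxels of the enclosing cell.
4. **Angles, CER, DMA** (`measure_angles()`, `cer()`, `dma()`): the
   sphere ∩ plane circle (`rho = sqrt(r^2 - d^2)`) is the pulley; the
   projected DIP and PIP give the two external tangents.
5. **Lateralization** (`lateralize()`): the fitted sphere is translated
   along world +X by 0, 6, 9 and 12 mm with its radius held fixed, and
   the slice geometry is re-measured. By default the humerus is *not*
   co-translated, matching the simulation protocol; the
   `translate_humerus` flag of `run_pipeline()` explores the
   alternative in which hardware lateralization carries the humerus
   with it and largely preserves the moment arm.

The deltoid moment arm is reported in two readings because the phrase
"distance between the ILSS centre and the line perpendicular to F1"
admits two constructions: the classical moment arm (perpendicular
distance from the joint centre to the MD line of action, which for a
tangent line is exactly `rho`) and the distance to the line through
the DIP perpendicular to F1. Neither is asserted to be the published
protocol; published DMA magnitudes depend on patient geometry we do
not have and are not reproduction targets.

## The synthetic shoulder

`shoulder_params()` / `generate_shoulder()` build a parametric right
shoulder in world millimetres (X mediolateral, lateral positive; Y
along the diaphysis; Z anterior): a glenosphere of configurable radius
(the published per-patient range is 25.7–39.4 mm), a cylindrical
diaphysis with the DIP on it, an acromial sphere carrying a horizontal
insertion arc with the four Sakoma sites, and a deltoid sheet of taut
fiber paths (straight segment – wrap arc – straight segment, computed
per fiber in the plane through the implant centre). Contact points lie
exactly on the sphere; normals follow the inward (towards the implant
centre) picking convention. Everything downstream therefore has a
closed-form oracle: `analytic_angles()` gives exact E, B, T per slice
and offset, and the ground-truth table carries CER, `rho` and both DMA
readings.

Default geometry: implant radius 33 mm at the origin; diaphysis along
+Y through (10, ·, 0) with radius 12 mm; DIP at (24, −78, −3); acromial
sphere at (−20, 21, 0) with radius 21.6 mm and its arc at height 18 mm
(arc radius 12 mm); sites at arc angles −50° (P1), −20° (M1), 10° (A3),
40° (A2). These values were chosen once, from the closed-form
construction, so that the 0 mm slice angles fall in the clinically
reported ranges (T ≈ 53–57°, E ≈ 7–9°, CER ≈ 0.48–0.61) and respond
monotonically to lateralization (T strictly falls, E and CER strictly
rise through 0 → 6 → 9 → 12 mm). The response is *weaker* than in the
published patients (T reaches ≈ 45–52° at 12 mm rather than ≈ 39–41°),
so lateralized-condition angle tables are properties (direction,
self-consistency), never value targets.

The arm position enters as `arm_angle`: the images fix 80° between
diaphysis and scapula, but how that maps to the DIP–implant
configuration is not observable, so deviations from 80° simply rotate
the humerus rigidly about the implant centre in the XY plane.

What the generator deliberately does **not** emulate: MRI physics
(artifacts, fat suppression), a realistic scapula, deltoid mass or
pennation, or inter-structure contact mechanics. Passing tests show
the *pipeline* is correct and self-consistent on geometry with known
truth — they do not validate the clinical model against real anatomy.

```{r, eval = FALSE}
p <- shoulder_params()
gen <- generate_shoulder(p)          # clouds + labeled volume + truth
res <- run_pipeline(p)               # fitted, resliced, measured
merge(res, gen$ground_truth$per_slice, by = c("slice", "offset"))
```

## Statistics

* `descriptives()` — mean, sample SD (n−1), min, max, rendered
  "mean±SD (min–max)".
* `mann_whitney_exact()` — two-sided Mann–Whitney by full enumeration
  of all `choose(n1+n2, n1)` assignments of the observed midranks for
  combined samples up to 20 (so ties are exact), doubling the smaller
  tail and capping at 1; a tie-corrected normal approximation with
  continuity correction beyond. At n = 7 per condition the smallest
  achievable two-sided p is 2/3432 ≈ 0.00058, the floor visible in
  published comparison tables. No multiplicity correction is applied
  (α = 0.05 per test), mirroring the analysis it reproduces.
* `icc_agreement()` — single-measure ICC from the two-way mean-squares
  decomposition. The published analysis does not state its ICC model;
  we default to ICC(2,1) (two-way random effects, absolute agreement —
  the appropriate choice for rater agreement on continuous
  measurements) and report ICC(3,1) alongside. The reliability
  protocol is simulated by warping the labeled volume with a smooth
  (coarse-grid, trilinearly upsampled) random displacement field —
  segmentation errors are spatially correlated, not i.i.d. voxel
  noise — then re-extracting the deltoid internal surface and
  refitting the ILSS. "3D model" agreement is operationalised as
  agreement on total segmented volume, since the published per-model
  ICC inputs are not recoverable.

## Numerical choices

* **Resampling kernel**: "eight neighboring pixels" is read as the 8
  corners of the enclosing voxel cell; `t` is normalised per axis by
  the voxel spacing and the per-axis weights are multiplied, which
  keeps the weights a partition of unity (`w(t) + w(1−t) = 1`).
  Integer labels are resampled by weighted majority (interpolating
  label codes directly is meaningless); an intensity channel is kept
  for display. Slice rasters default to 0.5 mm pixels over a 160 mm
  extent — the protocol never states raster parameters, these are
  chosen fine enough that raster error is negligible against the 3 mm
  acquisition spacing.
* **Normal filter convention**: the printed elimination rule ("scalar
  product over 0 → eliminated") is consistent with its stated intent
  only if internal-aspect normals point towards the implant; the
  `normal_sign` option makes the convention explicit (default
  `inward`) and the filter errors out if it would eliminate every
  point, which signals the opposite convention.
* **Stopping rule**: the published pruning is interactive ("with each
  click"); we fix `max_iterations = 5`, `radius_tol = 0.05` mm for
  reproducibility. Within the loop the algebraic fit is used, which
  makes the recorded loss provably non-increasing; the geometric
  refinement runs once at the end.
* **Signs and degeneracies**: CER is reported as a positive magnitude
  (tables print it positive; the derivation's minus sign only encodes
  that coaptation opposes elevation). E is unsigned; whether E should
  change sign if the MD line crossed the axis medially is not
  specified, and no synthetic configuration we generate does so.
  Tangent construction errors out for points inside or on the circle,
  collinear landmark triples, planes that miss the sphere, and
  parallel MD/proximal lines (no deflection).
* **Laterality**: right-shoulder convention throughout; left shoulders
  are mirrored at ingest (slice frames force lateral = +x).

## Problem sizes

The bundled analyses and tests run on: clouds of ~650 points per
patient (36 fibers × 18 samples), volumes of ~70 × 117 × 33 voxels at
(1.5, 1.5, 3) mm, seven-patient cohorts, 112-row result tables
(7 × 4 slices × 4 offsets), exact Mann–Whitney at n = 7 + 7, and
ICC simulations with 100 subjects × 2 raters. The brute-force tangent
oracle in the tests scans 10^6 candidate directions.

## Known limitations

* The synthetic lateralization response underestimates the published
  effect size; direction and self-consistency are tested, magnitudes at
  6–12 mm are not.
* Volume-derived radii carry a small positive bias (≈ 0.5 mm at the
  default voxel sizes) from voxel-face quantisation of the internal
  surface; it is constant across repeats and cancels in agreement
  statistics.
* The unpaired Mann–Whitney mirrors the published analysis even though
  the design (every patient measured under every condition) is paired;
  with synthetic between-patient variance the unpaired test is
  accordingly conservative.
* Mesh export (PLY/STL) is not implemented; clouds travel as CSV,
  volumes as NIfTI, spheres/parameters/ground truth as JSON.
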