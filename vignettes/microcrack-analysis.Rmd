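---
title: "Detecting and measuring microcracks in trabecular bone micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring microcracks in trabecular bone micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bone microdamage takes the form of microcracks: planar voids a micrometre
or so thick and tens to hundreds of micrometres across, produced by
physiological loading. In synchrotron micro-CT volumes of trabecular bone
at 1.4 um voxels they appear as faint dark sheets inside the mineralised
phase, weakly contrasted because their thickness is on the order of one
voxel (partial volume), and further obscured by noise and concentric ring
artifacts. The other abundant porosity at this scale, the osteocyte
lacuna, is a compact ellipsoidal cavity roughly 10-25 um across; any
microcrack analysis must separate the two populations.

`microcrackct` implements the full analysis chain: pre-processing,
planarity-based crack enhancement, hysteresis segmentation, 3D
morphometry of every porosity, microcrack/lacuna classification,
specimen-level summaries, and virtual 2D sectioning for comparison with
histology-style measurements. A synthetic phantom generator with
voxel-level ground truth makes every stage testable without image data.

## Pipeline model, stage by stage

**Pre-processing.** Ring artifacts are concentric grey-level rings about
the reconstruction axis, caused by non-uniform detector response. Each
slice is resampled to polar coordinates (bilinear interpolation, dense
angular grids every quarter voxel of radius) and the angular median gives
a radial profile in which rings survive but anatomy largely averages out.
The low-frequency part of that profile -- a least-squares natural-spline
fit with knots every `radial_smooth_um` (default 42 um) -- is anatomy;
the remainder is the ring estimate. Because the fit is a projection, the
correction is idempotent. Per-slice estimates are combined by a
per-radius median across slices, and a consistency gate (consensus must
exceed 1.5 x the cross-slice MAD) refuses to subtract radial patterns
that fluctuate from slice to slice, i.e. anatomy. The gate is
deliberately conservative: in thin stacks whose anatomy is strongly
correlated along z it also suppresses part of a genuine ring, whereas in
acquisition-scale stacks (a thousand slices and more) rings pass easily.
The estimate-subtract cycle runs twice so that a second external
application changes essentially nothing.

Global intensity variation is modelled as a quadratic polynomial field
fitted to bone-phase grey values and removed by subtraction (or
division). A low-order trend is exact on scanner-scale drifts including
at the volume boundary, is the identity on unbiased volumes, and leaves
local anatomy (mineralisation bands, cement lines, porosities)
untouched; a moving-average bias field has neither property.

**Bone and envelope.** Mineralised bone is segmented by a single global
threshold (inter-class-variance criterion when set to `"auto"`), which
the high phase contrast of the acquisitions justifies. The trabecular
envelope -- the filled solid of the trabeculae -- is a morphological
closing with a 14 um ball followed by cavity filling; the closing runs on
a background-padded grid, which reproduces unbounded-space morphology
exactly, so bone cut by the volume faces is neither inflated nor eroded.
Porosities are voxels of the envelope that the segmentation assigns to
voids; the final bone phase is the thresholded mask minus those
porosities, because partial-volume crack voxels can lie above the grey
threshold.

**Planarity enhancement.** At scale `planarity_sigma_um` (default 2.1 um
= 1.5 voxels) the Hessian of the Gaussian-smoothed volume is diagonalised
at every voxel. Sorting eigenvalues by magnitude, `|h1| >= |h2| >= |h3|`,
a thin dark sheet in bright material gives a large positive `h1` (a grey
minimum across the sheet) with small `|h2|, |h3|`; a compact dark blob
gives three comparable eigenvalues and a bright structure gives negative
`h1`. The sheetness score `h1 * exp(-(h2^2 + h3^2) / (2 (alpha h1)^2))`
(alpha = 0.5) is normalised to `[0, 1]` by its 99.9th percentile so that a
single extreme voxel cannot flatten the rest of the volume. The
eigenvector of `h1` is the sheet normal.

**Planarity-guided filtering.** A bilateral-type filter replaces each
envelope voxel by a weighted mean of its neighbours within
`spatial_radius_um` (default 2.8 um), the weights being the product of a
spatial Gaussian, a Gaussian in planarity-score difference (bandwidth
0.2) and a Gaussian in grey difference. Crack voxels share high, similar
planarity and similar dark greys, so they average with each other --
suppressing noise along the crack without bleeding grey values across the
crack-bone interface. With infinite bandwidths the filter degenerates to
plain truncated-kernel Gaussian smoothing, a limit the tests exercise.

**Hysteresis segmentation.** The enhanced volume is converted to a
porosity response in `[0, 1]`: grey darkness below the bone threshold,
scaled by the bone-marrow contrast, combined (by maximum) with the
planarity score so that partial-volume crack voxels whose grey barely
drops are still candidates. Voxels above `hysteresis_high` (default 0.5)
seed a flood through all voxels above `hysteresis_low` (default 0.3)
under 26-connectivity; thin tilted sheets disconnect under
6-connectivity, hence 26 for porosities (bone keeps 6). Components that
are mostly within two voxels of the envelope exterior are sealed surface
concavities created by the closing, not internal porosities, and are
dropped. The exposed tuning surface is deliberately small -- bone
threshold, planarity scale, the two hysteresis levels and the filter
radius -- and the defaults were chosen by detection recall and precision
on phantoms, the only ground truth available.

## Per-object morphometry

* **Volume**: `Cr.V = N * voxel^3`, exact by construction.
* **Length and width**: the centered second-order moment matrix of the
  voxel centres is diagonalised and the semi-axes of the uniform solid
  ellipsoid with the same moments are `a_i = sqrt(5 lambda_i)`;
  `Cr.Le = 2 a1`, `Cr.W = 2 a2`. The `sqrt(5 lambda)` closure is the
  standard moment relation for a solid ellipsoid and recovers the axes of
  digitised ellipsoids to better than 2%. Because cracks can twist,
  `2 a3` is not a usable thickness.
* **Thickness**: the direct (model-free) local thickness. For every
  object voxel `c` the Euclidean distance transform gives the radius
  `r(c)` of the largest open ball around `c` inside the object; every
  voxel within that ball receives at least the calibrated diameter
  `2 r(c) - 1` voxels (exact for digitised balls and slabs), and `Cr.Th`
  is the mean over the object. Sphere centres whose ball lies inside a
  neighbour's ball are pruned before painting, which changes nothing in
  the result but makes large volumes tractable.
* **Surface**: `Cr.S = Cr.V / Cr.Th`, the area of the equivalent sheet of
  uniform thickness. On the printed reporting scale (1e-3 mm^2) values
  are truncated -- not rounded -- to two decimals, matching the
  convention of the published per-crack tables that this package's
  consistency checks reproduce.
* **Classification**: a porosity is a microcrack when `Cr.V > 500 um^3`
  and `Cr.Th / Cr.W < 1/3`; above the volume cut but failing the ratio it
  is a lacuna; anything at or below 500 um^3 is `other` (unresolved
  porosity or noise). A zero width makes the ratio undefined and the
  object `other`.
* **Local trabecular context**: `Tb.Th.lo` is the mean envelope thickness
  over a site window (a ball of radius `max(Cr.W, 50 um)` about the crack
  centroid -- "at the site of the crack" needs a concrete window, and one
  crack-width is the natural scale). The local shape is read from the
  same window: three or more separate envelope patches on the window
  shell mean the trabecula branches there (junction); otherwise window
  moments separate rod (elongated) from plate. This is a simplified
  stand-in for full topological classification and is flagged as such in
  reports.

**Specimen level.** `BV` is the bone-phase volume (envelope minus
porosities), `TV` the analysed volume; crack and lacunar densities are
counts per `BV` in 1/mm^3, each object counted once however many slices
it crosses. Means and SDs over microcracks use the population SD. SMI is
computed from offset volumes: with `V(r)` the volume of the structure
offset by a signed distance `r` (sampled from the exact signed EDT with
partial-volume counting, which removes the lattice staircase), a cubic
fit -- exact for planes, cylinders and spheres -- gives `S = V'(0)` and
`S' = V''(0)`, and `SMI = 6 V S' / S^2`: 0 for plates, 3 for rods, 4 for
spheres. Structures clipped by the grid behave as unbounded, which is the
correct reading for specimens that span the field of view.

## Virtual 2D sections

`make_virtual_sections()` averages `slices_averaged` consecutive slices
(default 5, i.e. 7 um at 1.4 um voxels) every `spacing_slices` (default
128 = 180 um) to emulate thick histological sections, starting at a
configurable offset `z0` (default 0). The 2D chain mirrors the 3D one per
section; traces large and elongated enough (area > 50 um^2,
minor/major < 1/3) count as crack sections. Trace length uses the
thin-strip moment closure `a1 = sqrt(3 lambda1)`, exact for a uniform
line segment, because traces are line-like rather than elliptical. A
crack crossing k sections is counted k times and a crack between
sections is missed -- the two mechanisms that bias section-based
histomorphometry and that the 3D analysis avoids. The 2D crack density
divides the pooled trace count by the pooled 2D bone area; this
convention reproduces published section densities from published counts
and bone fractions to within 10%, which is the reason it was adopted.

## The phantom generator

The generator is the package's study condition, not a tuning knob. It
emulates, with voxel-level ground truth:

* trabecular architecture as a thresholded smoothed random field
  (periodic-boundary smoothing keeps the field stationary to the volume
  faces; the threshold is the exact BV/TV quantile), with plate/rod/mixed
  anisotropy modes and optional explicit plate/rod primitives;
* heterogeneous mineralisation: slow multiplicative grey bands (5%
  default) and darker cement-line shells at a fixed depth in bone;
* lacunae as randomly oriented ellipsoids (semi-axes 9-13 x 5-7 x
  3.5-5 um), placed fully interior to the bone phase;
* cracks as flattened solid ellipsoids (lenses) 88-250 um long,
  48-130 um wide and 1.4-7 um at their thickest, clipped to bone,
  optionally twisted, crossed or in parallel pairs; a one-voxel floor
  keeps even the rim representable. The default 256^3 grid at 1.4 um
  spans 358 um, so lengths are capped at 250 um (the published range
  extends to ~500 um, which cannot fit this grid);
* image degradation: one-voxel Gaussian blur (partial-volume surrogate),
  Gaussian noise (default 10% of the bone-marrow contrast) and a
  concentric sinusoidal ring pattern.

Distinct truth objects keep a 5 um clearance (`min_separation_um`):
parameter recovery is only meaningful when each porosity is an isolated,
individually measurable object. Each crack record stores both its nominal
parameters and the realised voxel set's own moment length/width and mean
direct thickness; recovery tests compare the pipeline against the
realised object, because clipping to bone and the lens profile make the
nominal scalars differ from the true object's morphometry even under
perfect segmentation.

What the phantom does not emulate: diffuse sub-voxel damage, anatomical
plate/rod networks, beam hardening and phase-contrast fringes, spatially
correlated noise. Passing the phantom benchmarks therefore demonstrates
correct mechanics and robustness to the modelled degradations, not
clinical-grade performance on arbitrary scanners.

## Validation scale and known limitations

The validation suite runs at desk scale: oracle comparisons (brute-force
moments, exhaustive sphere fitting, flood-fill hysteresis) on objects up
to 32^3, geometry checks on 40-110 voxel grids, and full parameter
recovery on 256^3 phantoms with 20 cracks and 30 lacunae at zero and 10%
noise. At those conditions the pipeline reaches 0.95 crack recall
(50% voxel-overlap criterion), ~5% median length error and under half a
voxel median thickness error; those are the numbers the acceptance tests
assert, and they are recomputed on every run.

Known limitations:

* one-voxel-thin cracks at partial volume sit at the detection limit;
  the thinnest cracks account for the recall below 1;
* the ring-artifact consistency gate suppresses genuine rings in thin
  stacks with strongly z-correlated anatomy (it never harms anatomy);
* the moment-based length over-estimates the extent of a uniform thin
  disk by ~12% (the solid-ellipsoid closure is exact only for the lens
  profile); this is a property of the estimator, shared with the field's
  convention, not of the implementation;
* surface-open porosities are deliberately discarded; cracks reaching
  the trabecular surface lose their surface-adjacent rim;
* the trabecular shape call is a window-based heuristic, not a full
  topological classification.
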