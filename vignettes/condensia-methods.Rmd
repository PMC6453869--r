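---
title: "Quantifying mesenchymal condensations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesenchymal condensations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensia)
```

Mesenchymal condensation — the aggregation of mesenchymal cells into dense
masses — is the first morphological step of cartilage and bone formation.
`condensia` quantifies condensations in two imaging settings: brightfield
images of micromass cultures, where condensations appear as dark masses on a
bright background, and live fluorescence imaging of cultures confined in
rectangular microgrooves, where condensations appear as peaks of nuclear-stain
intensity along the groove. This vignette explains the models behind each
pipeline, the parameters that matter, and the design choices made where the
problem left them open.

## Micromass segmentation

`segment_micromass()` composes three stages.

**Preprocessing** (`preprocess()`). RGB images are converted to grayscale with
Rec.709 luma weights, rescaled to [0, 1], and polarity-normalized so that
condensations are dark (a `polarity = "bright"` flag inverts inputs first;
because the inversion happens before any nonlinear step, an inverted image
with the flag flipped yields an *identical* label map). Local contrast is
enhanced with contrast-limited adaptive histogram equalization (CLAHE,
nominal tile size `clahe_tile` = 32 px, contrast limit `clahe_clip` = 2 in
multiples of the uniform histogram height) and constant-power additive noise
is attenuated with a Gaussian low-pass (`lowpass_sigma` = 2 px). Tile size
and clip are mild defaults for stereoscope-scale images; both are exposed
because staining and illumination vary widely between rigs.

**Binarization and cleaning** (`binarize_and_clean()`). A global Otsu
threshold separates dark foreground from bright background. Before accepting
it, the pipeline checks Otsu's separability measure — the fraction of total
intensity variance explained by the two-class split. A threshold cut through
unimodal noise cannot exceed about 0.64 (the Gaussian limit), while images
genuinely containing dark objects score above roughly 0.85, so the default
`min_separability = 0.75` makes a blank noisy field segment to zero objects
instead of a constellation of noise blobs. Morphological opening (disc,
radius 2 px) removes specks, closing (radius 2 px) fills small holes,
8-connected components with fewer than `min_object_px = 24` pixels are
removed (strictly fewer: a 24-pixel component survives), and structures
connected to the image border are suppressed — border-touching masses are
partially out of frame and would bias every shape descriptor.

**Watershed with minima imposition** (`split_touching()`). Touching
condensations are split by a watershed on the negated Euclidean distance
transform. A plain watershed over-segments, because every local minimum
seeds a basin; basins are therefore kept only where the distance transform
rises at least `minima_depth_h` (default 2 px) above the saddle to a
neighbouring basin, which is exactly the extended-minima/minima-imposition
construction. The default splits overlapping disk pairs whose neck is
noticeably narrower than the lobes while leaving mildly waisted single
objects intact; the unit tests construct both geometries from the
closed-form saddle depth $r - \sqrt{r^2 - (d/2)^2}$ of two radius-$r$ disks
$d$ apart.

## Shape descriptors

`descriptor_table()` reports eleven descriptors per condensation: area,
perimeter, eccentricity, minor and major moment-ellipse axes, aspect ratio
(major/minor, ≥ 1 by construction), roundness, the number of condensations
in the image, boundary roughness, the mean centroid distance to the four
nearest neighbours (averaged over the available neighbours when fewer than
four exist), and occupancy. Axes and eccentricity come from the ellipse with
the same normalized second central moments as the region (with the standard
1/12 per-pixel variance correction), so a circle has eccentricity 0 and a
line segment approaches 1.

The three composite descriptors deserve their numerical details:

* **Roundness** is $4A/(\pi \cdot \text{Major}^2)$: 1.0 for a perfect
  circle, approaching 0 for elongated shapes.
* **Roughness** is convex perimeter divided by perimeter: 1 for convex
  objects, below 1 for branched or irregular boundaries. Perimeter is
  measured on the traced boundary polygon after a 5-point circular moving
  average. Raw pixel-chain perimeters overestimate a circle's circumference
  by about 5% (the staircase effect), which would push convex objects'
  roughness to ~0.95; after smoothing, disks and rotated rectangles measure
  within 0.5% of 1. The convex perimeter uses the hull of the *smoothed*
  contour, which guarantees roughness ≤ 1 exactly. Regions too small to
  trace (single pixels, short lines) are defined as convex.
* **Occupancy** selects the circle whose diameter joins the region's two
  most distant pixels and reports the fraction of that circle's lattice
  pixels covered by the region: ≈ 1 for a disk, ≈ $4/(\pi d)$ for a thin
  segment of length $d$. The circle radius is corrected by +0.25 px because
  pixel centres sit, on average, about a quarter pixel inside the
  continuous extremes at each end; without the correction occupancy is
  biased by ±2–3% on desk-scale shapes. Validation compares all three
  descriptors against a continuous polygon-geometry oracle (shoelace area,
  Green's-theorem moments, exact hull perimeter) on rasterized convex
  polygons and requires 2% agreement.

**Descriptor ranking.** `fit_discriminant()` implements the two-class Fisher
discriminant on jointly standardized descriptors:
$w = S_W^{-1}(\bar{z}_a - \bar{z}_b)$ with $S_W$ the pooled within-class
covariance and equal priors. Because the predictors are standardized
(mean 0, unit sd, $n-1$ denominator), $|w_j|$ measures descriptor $j$'s
contribution to the separation, and the result's `ranking` orders
descriptors accordingly — this reproduces the feature-ranking use of LDA for
face versus limb-bud condensations. A ridge term ($10^{-6}\,\mathrm{tr}\,S_W$
on the diagonal) stabilizes near-singular covariances; the direction is
cross-checked against `MASS::lda` in the test suite. Standardization is
performed jointly across both classes; a constant column is a hard error in
`standardize()` (it carries no information and makes scaling undefined),
and the end-to-end pipeline drops such columns with a message — the
image-level `n_condensations` descriptor is constant whenever all analysed
images happen to contain the same number of objects. Whether LDA weights
are attributable descriptor-by-descriptor depends on their correlation:
shifting the generator's area range necessarily co-shifts perimeter and
axes, so weight-recovery validation uses simulated descriptor populations
in which the class separation is confined to a known descriptor.

## Groove quantification

The groove pipeline is profile-based by construction. For each groove ROI,
fluorescence is averaged across the minor axis to give a 1-D intensity
profile along the groove (`axial_profile()`); condensations are the peaks of
this profile (`detect_condensations()`), their **length** is the full width
at half maximum (FWHM) of the peak, their **width** is the FWHM of the
perpendicular profile averaged only over the peak's half-max interval
(`measure_condensation()`), and their cell density is summarized by
topographic **peak prominence** — the height of a peak above the higher of
its two key saddles. Prominence rather than absolute intensity is compared
across time because nuclear-stain intensity accumulates over a live series,
shifting the baseline of every frame.

Numerical choices:

* **Noise floor and detection threshold.** The profile noise level is
  estimated robustly as 1.4826 × MAD of the scaled second difference
  $(y_{i-1} - 2y_i + y_{i+1})/\sqrt{6}$. Second differencing removes locally
  linear signal (the smooth flanks of condensation peaks); a running-median
  residual was rejected because it is exactly zero on monotone stretches
  and its MAD collapses. The default `min_prominence` is **6×** this noise
  level: across profiles of several hundred samples the most prominent pure
  noise excursions empirically reach 4–5σ, so a 3σ floor admits roughly ten
  spurious peaks per groove while 6σ rejects them and still sits far below
  the prominence of any resolvable condensation.
* **Half-maximum reference.** Within one frame, the groove background is
  estimated as the 10th percentile of the major-axis profile (the level
  between condensations, which also tracks accumulation offsets), and the
  FWHM level is $(\text{height} + \text{background})/2$. Referencing the
  prominence base instead biases the FWHM low whenever a condensation is
  truncated by the groove edge or overlaps a neighbour, because the base
  itself is then elevated; with the background reference, recovered lengths
  and widths stay within 5% down to moderate truncation. Crossings are
  linearly interpolated and confined to the peak's basin (between its
  flanking key minima); a peak whose half-max level is not reached before
  the basin bound or profile end is flagged `clipped`, and measured widths
  are additionally capped at the groove's short-axis extent — a
  condensation cannot be wider than its groove.
* **Aspect-ratio convention.** In constrained grooves (below 300 µm) the
  aspect ratio is length/width along the groove axes and may fall below 1
  when a condensation grows wider than long. In 300 µm grooves and on
  unconstrained tissue-culture plastic no axis is privileged, so the ratio
  is longest/shortest and is ≥ 1 by definition.
* **Backward tracking.** Condensations are identified in the final frame
  and tracked backwards; each track links to the nearest-position peak in
  the previous frame, greedily by distance with exclusion, gated at
  `max(10 µm, 0.5 × current length)`. A track ends (backwards) when no
  gated match exists; that frame is its establishment time. The number of
  tracks always equals the number of final-frame condensations.
* **Plateau time.** Per-timepoint means are computed over condensations,
  and the plateau time of a metric is the earliest timepoint from which it
  stays within ±10% of its final value through the end of the series. For
  logistic growth the band-crossing time is available in closed form
  (`logistic_plateau_time()`), which is what the validation compares
  against.
* **Marker fractions.** `marker_positive_fraction()` counts nuclei as local
  maxima of the nuclear channel above a detection threshold (Otsu by
  default) and reports, per condensation region, the fraction whose marker
  intensity reaches the marker threshold — e.g. the ratio of Sox9-positive
  to total nuclei.

## The synthetic generator

Because validation needs exact ground truth, `condensia` ships a generator
rather than fixtures. `generate_micromass_scene()` renders dark ellipses (or
branched unions of a core and 2–3 overlapping arm ellipses, emulating the
branched morphology of facial condensations) on a bright background with
additive Gaussian noise (a Poisson shot-noise mode is available), subject to
a minimum envelope gap; rejection sampling raises an explicit placement
error when the requested packing is infeasible. `generate_groove_series()`
renders condensations as additive 2-D anisotropic Gaussians whose length
and width FWHMs follow logistic growth
$F(t) = F_\infty / (1 + e^{-r(t - t_m)})$ and whose peak amplitude ramps
linearly across the series. The logistic is the minimal saturating growth
law consistent with condensations that stop growing after an initiation
phase; with the default midpoint 8 h and rate 0.25 h⁻¹ the size enters its
±10% plateau band around 17 h, matching the timescale on which real
condensations stabilize. Defaults describe a 100 µm × 500 µm groove at
1 µm/px imaged every 30 min for 36 h (72 frames), with one condensation per
100 µm; pixel calibration is configurable everywhere since it depends
entirely on the microscope.

What the generator deliberately does **not** emulate: brightfield optics
(phase halos, uneven illumination), cell-scale texture inside
condensations, drift between frames, and non-Gaussian condensation
profiles. Passing the validation suite therefore demonstrates that the
measurement chain is correct and unbiased on well-posed inputs, not that
segmentation is robust to every artefact real microscopy produces; the
configurable preprocessing stage is where such robustness is tuned per
dataset.

## Validation problem sizes

The test suite validates, among others: exact label-count recovery on 100
seeded 256×256 scenes of six 300–700 px² objects at noise sd 0.03 (≥ 95%
required); FWHM length/width recovery on 100 seeded single-frame grooves at
pixel SNR 10 with peak separation ≥ 1.5 × FWHM (median relative error ≤ 5%,
count exact in ≥ 95%); top-rank recovery of a known shifted descriptor over
100 simulated populations (≥ 90%); plateau-time recovery within ±2 h of the
analytic logistic crossing on 72-frame series; descriptor agreement within
2% of the polygon oracle; and the constraint-regime demonstration that
width-capped growth in 25/100/300 µm grooves yields a strictly decreasing
aspect-ratio ordering. These sizes keep the whole suite under a minute on a
laptop while leaving each property statistically meaningful.

## Known limitations

* Global Otsu assumes reasonably uniform illumination; strongly vignetted
  images should be flat-fielded upstream.
* The profile-based groove quantifier cannot separate two condensations at
  the same position along the groove but different transverse positions;
  this follows from the axis-averaging model itself.
* Tracking is nearest-neighbour with gating — adequate for slowly moving,
  well-separated condensations, not for dense crossing trajectories.
* Descriptor weights from the discriminant are directions in correlated
  descriptor space, not causal attributions.
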