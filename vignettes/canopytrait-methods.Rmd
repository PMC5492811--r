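---
title: "Methods: canopy trait monitoring from two-level narrow-band sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy trait monitoring from two-level narrow-band sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytrait)
```

This vignette documents the models behind `canopytrait`, the assumptions
they rest on, the tunable parameters with their defaults, the numerical
choices made where the methodology leaves latitude, and what the synthetic
experiment does and does not establish.

## The monitoring problem

Two optical sensing levels observe the same field experiment: a UAV-borne
imaging spectrometer (bands every 10 nm, 450–910 nm, ~0.2 m pixels covering
whole plots) and a handheld radiometer (11 bands, 490–870 nm, four ~0.5 m
footprints per plot placed directly over crop rows). Both deliver
narrow-band reflectance from which vegetation indices are computed and
related to four crop traits: leaf chlorophyll content (µg cm⁻²), plant/leaf
area index (m² m⁻²), canopy chlorophyll content (g m⁻², the product of the
first two with a 0.01 unit factor) and fractional ground cover. Because the
ground sensor samples preferentially over the rows while the UAV averages
rows and inter-row soil, the two streams differ most when the canopy is
open — the central comparability question the comparison statistics
quantify.

## Vegetation indices

All 16 indices are evaluated on plot-aggregated spectra (band-wise weighted
means; the four ground footprints are equally weighted, since no rationale
exists for unequal ones). Nominal band centres are resolved to the nearest
sensor band within a tolerance (default 10 nm, ties to the shorter
wavelength), which accommodates the small per-sensor differences in anchor
bands: the ground radiometer supplies 780 nm where the formula family is
written for 800 nm, and its MTCI uses 670/710/750 nm against nominal
681/709/754 nm. Two transcription decisions deserve note:

* **CI_g** is computed as R780/R550 − 1: the formula and its textual
  description (a green band replacing the 710 nm red-edge band of CI_re)
  are self-consistent, while the accompanying band list (710, 750) is a
  typographical duplicate of the CI_re row.
* **MCARI2** uses the published form with the radicals,
  1.5·[2.5(R800−R670) − 1.3(R800−R550)] / √((2R800+1)² − (6R800 − 5√R670) − 0.5).

Undefined values (zero denominators, the MCARI2 discriminant ≤ 0, masked
input) propagate as `NA` rather than errors, so a single bad pixel cannot
abort an index map. Only the genuinely ratio-based formulations (NDVI,
CI_re, CI_g, MTCI, PRI, REP) are invariant under a positive rescaling of
the spectrum; WDVI, MCARI and TCARI are homogeneous of degree one, and the
soil-adjusted forms (OSAVI and derivatives, MCARI2) are neither, because of
their additive constants. The test suite asserts exactly these behaviours.
WDVI needs a soil line C = RSoil870/RSoil670; there is no hard default — C
is always derived from soil spectra (`estimateSoilLine()`), in synthetic
runs from the generator's own soil endmember.

## Canopy structure from hemispherical photographs

Downward hemispherical photographs are segmented into vegetation and
background, binned into gap fractions on a fixed angular grid, and inverted
for plant area index (PAI), average leaf inclination angle (ALA) and a
clumping profile.

**Segmentation.** The excess-green channel 2G − R − B is thresholded by
between-class-variance maximisation (Otsu). This simplification of
colour-transform threshold optimisation is adequate for green canopy over
soil; senescent (brown) vegetation will be classified as background, which
is consistent with the optical definition of the retrieved quantity but
understates structure late in the season.

**Angular grid.** 15 zenith rings of 2.5° covering 0–37.5° (the usable
range of the camera–lens combination) by 72 azimuth cells of 5°. The
default pixel-to-angle mapping is an ideal equidistant fisheye (zenith
proportional to radial distance); a calibrated projection can be supplied
as a function. Each cell records its non-masked pixel count, and every
average in the chain is count-weighted, including across photographs with
unequal valid-pixel counts.

**Model.** The gap fraction at zenith θ follows the Poisson model
P(θ) = exp(−G(θ, χ)·Ω·L/cos θ) with the ellipsoidal leaf inclination
distribution: G(θ, χ) = cos θ √(χ² + tan²θ) / (χ + 1.774(χ + 1.182)^−0.733)
and the closed-form ALA ≈ 9.65(3 + χ)^−1.65 (radians), inverted
analytically. At χ = 1 this gives G = 0.4997 at every angle (spherical
limit). Azimuthal uniformity of the projection is assumed. Because optical
inversion cannot separate leaves from stems and senescent parts, the
retrieved quantity is a plant area index; "LAI" downstream refers to this
clumping-adjusted PAI.

**Clumping.** Per ring, Ω(θ) = ln(weighted mean cell gap) / (weighted mean
of ln cell gap) — the logarithmic gap-averaging estimator, which responds
to between-cell heterogeneity and equals 1 for homogeneous rings (by
Jensen's inequality it cannot exceed 1; the implementation clips at 1 and
returns 1 for the empty-canopy 0/0 case). Fully vegetated cells, where the
logarithm is undefined, are replaced by the saturated gap fraction computed
at PAI = 10 m² m⁻² with a candidate *effective* ALA; all gaps are clipped
to [P_sat, 1] before logs for the same reason.

**Inversion.** A full look-up-table search over PAI 0–10 in 0.01 steps,
ALA 10–80° in 2° steps, and the same 2° grid of effective ALAs governing
the saturation replacement: 1001 × 36 × 36 candidates. The per-ring Ω(θ)
profile of the candidate effective ALA is used inside the model (the
estimator is θ-indexed, so a scalar Ω would discard information). The cost
is the count-weighted root-mean-square difference between measured
(saturation-replaced) and modelled ring gap fractions — the simplest
reading of a weighted gap-fraction matching cost; exact ties are broken
toward the lowest PAI, then the lowest ALA, then the lowest effective ALA,
making the search deterministic. The vectorised search is verified in the
tests against an independently coded brute-force triple loop. Ground cover
is one minus the count-weighted mean raw gap over the rings fully inside
the 0–20° cone (rings 1–8).

Identifiability caveat: near the spherical distribution G is almost
flat in θ, so ALA is weakly identified from a 0–37.5° window — small noise
moves the ALA estimate more than the PAI estimate, which the noise-free
tolerance of one 2° grid step in the tests reflects.

## Retrieval and comparison statistics

Traits are regressed on indices by ordinary least squares. Accuracy is
reported as the mean RMSE of repeated (default 100×) 10-fold
cross-validation: each repeat draws a fresh uniform random partition into
10 near-equal folds (reseeded per repeat from a root seed), squared
held-out errors are pooled across folds *within* a repeat before taking the
root, and repeats are averaged — stated explicitly because several pooling
conventions exist. R², confidence and prediction bands (t-quantile
formulas, default 95%) and per-date mean errors are computed on the full
fit only; intervals are not re-estimated per fold. Mean errors use the
observed − predicted sign convention, so positive values mean
underestimation by the model.

Cross-sensor comparability of an index is summarised by regressing
ground-sensor values on UAV values over plot × date pairs and reporting
R² and the discrepancy of slope DS = 1 − slope (0 = slope-consistent with
the 1:1 line). The direction is a convention; a `flip` argument reverses
it, and the two directions are not reciprocal on noisy data. A date filter
allows excluding early acquisitions; the default keeps all dates.

Treatment discrimination uses the Bhattacharyya coefficient of the normal
distributions fitted (sample mean, n−1 sd) to each treatment's index
values. The coefficient is computed as BC = ∫ √(t₁ t₂) dx — with the
radical, which is what bounds BC in [0, 1] and makes 1 − BC a separability
score ranging from total overlap (0) to complete separation (1). The
numeric integral (adaptive quadrature over ±10 sd, rel. tol. 1e−10) is
checked against the normal–normal closed form
√(2s₁s₂/(s₁²+s₂²))·exp(−Δµ²/(4(s₁²+s₂²))) to 1e−8.

## Solar and footprint geometry

`solarPosition()` implements the NOAA/Meeus solar ephemeris (geometric
position plus standard refraction), accurate well under 0.1° in
1900–2100, with azimuth clockwise from north; the tests cross-check it
against an independently coded PSA algorithm to 0.2°. The footprint of a
conical-FOV sensor is diameter = 2h·tan(FOV/2); at 28° and 1 m this gives
0.499 m and 0.195 m².

## The synthetic experiment

The generator reproduces the *statistical structure* the analysis assumes,
not any particular field's numbers:

* **Design.** 3 blocks × 2 treatments ("non-mixed", "mixed") × 2 replicates
  = 12 plots of 3 m × 10 m in a strip with 5 m buffers; five acquisitions
  at 43, 62, 75, 84 and 99 days after planting.
* **Traits.** Leaf chlorophyll declines linearly (55 → ~39 µg cm⁻²); PAI
  follows a rise-plateau-decline (0.4 → ~3.5 → ~2.9 m² m⁻²); "mixed" plots
  lose an extra 1.0 m² m⁻² of PAI and 3 µg cm⁻² of chlorophyll on the last
  date, emulating late-blight incidence. Gaussian measurement noise
  defaults to 2 µg cm⁻² and 0.25 m² m⁻². Ground cover is 1 − exp(−0.5·PAI),
  the nadir Poisson gap with spherical G.
* **Spectra.** A deterministic parametric reflectance model (Beer-type
  chlorophyll darkening of the visible baseline, a green bump at 550 nm, a
  logistic red edge at 720 nm, an NIR plateau saturating in PAI) stands in
  for a radiative-transfer model. It preserves the ranks and shapes the
  indices respond to; absolute magnitudes are nominal, and no attempt is
  made to reproduce measured reflectance levels. Observations are linear
  vegetation/soil mixtures: UAV pixels use f = ground cover; the four
  ground footprints use f = min(1, ground cover × rowConcentration), with
  rowConcentration = 1.3 carrying the preferential row-sampling contrast
  (ground NDVI ≥ UAV NDVI while the canopy is open). Additive spectral
  noise defaults to sd 0.01.
* **Gap fields.** Per ring, a two-component cell mixture — a fraction p of
  full gaps (between-row holes) and denser cells at gap exp(−k/(1−p)),
  k = G·PAI/cos θ — with p solved numerically (bisection to 1e−12) so that
  logarithmic gap averaging on the noise-free field returns the target Ω
  exactly while ring means obey the clumped Poisson model. Cell weights are
  real-valued so the calibration is exact; four photographs of 72 cells per
  ring are generated.
* **Mosaics.** Rectangular plots at a vegetation-index level of 0.6 over
  0.1 soil, 0.2 m pixels, Gaussian noise sd 0.02 — the contrast regime the
  Canny extraction is specified for.

Everything is a pure function of (configuration, seed), with per-stage
substreams derived from one root seed; identical runs are byte-identical.

What passing tests on this generator shows: the estimators are correct on
data satisfying their own assumptions (Poisson gaps, linear mixtures,
normal errors) at the study's sample sizes. What it does not show:
robustness to real-world violations — non-random leaf dispersion beyond
between-cell clumping, directional reflectance and illumination effects,
georeferencing distortion, mixed senescent material — which is why the
package separates the generator from the estimators it exercises.

## Plot extraction choices

Canny parameters follow the documented workflow: Gaussian sigma 0.5 px,
and per-segment thresholds with the high threshold equal to the segment's
mean gradient magnitude ("directional gradient intensities" read as
gradient magnitude after smoothing, the standard Canny vocabulary) and the
low threshold 40% of it; the image is divided into four segments along the
strip axis. Non-maximum suppression uses 4-quantized gradient directions
and hysteresis keeps weak components connected to a strong pixel. Only the
across-strip (column) sides of each nominal rectangle are refined — to the
strongest edge column within a ±3 px window, requiring edge support on at
least 30% of the plot's rows; otherwise the nominal side is kept with a
warning. The original workflow's visual confirmation step is replaced by
this deterministic snap-plus-fallback so runs are reproducible. Pixel
membership of a rectangle is by pixel-centre containment, half-open on the
upper edges, making counts deterministic and adjacent plots disjoint.

## Problem sizes and runtime

The suite runs at desk scale by design: 50 noise-free inversions for the
recovery property (full 1001 × 36 × 36 table, ~0.3 s each), 20 seeded
mosaics for the boundary-accuracy property, 600 observations for the
known-noise cross-validation check, and a reduced pipeline configuration
(1 block, 3 dates, coarse LUT) for the determinism test. The complete
suite finishes in well under a minute on one CPU.

## Known limitations

* The spectral forward model is a stand-in; conclusions about absolute
  index values or reflectance magnitudes do not transfer to field data.
* ALA is weakly identified near the spherical distribution (see above).
* Segmentation assumes green vegetation on brighter soil; inverted
  contrast or senescent canopies need a custom threshold.
* The ENVI-dialect cube format stores doubles only; no compression, no
  GeoTIFF tags.
* No radiometric calibration or georeferencing is provided; inputs are
  assumed to be reflectance in a common geometry.
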