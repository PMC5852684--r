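---
title: "Reconstructing past forest cover with modern analogs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing past forest cover with modern analogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

The Modern Analog Technique (MAT) is a space-for-time transfer
function. Its single substantive assumption is that compositionally
similar pollen assemblages derive from similar vegetation, so an
environmental property measured around a modern sample — here, percent
forest cover — can be transferred to a fossil sample with a similar
assemblage. Everything else in the pipeline exists to make that
transfer honest: the calibration stage controls *what* "cover around a
sample" means, quality filtering controls *which* modern samples are
trustworthy pairings, PFT scoring controls *how* similarity is
measured across time (fossil floras contain taxon mixtures with no
modern counterpart; functional types blur taxonomy while preserving
structure), and bias correction compensates for the modern landscape's
thin representation of dense forest.

The assumption fails, by construction, wherever no modern vegetation
resembles the past one. The method does not hide this: a fossil sample
whose nearest analog exceeds the dissimilarity threshold is flagged
`no_analog` and contributes no value.

## Stage-by-stage parameters

### Kernel calibration (`extract_cover`, `select_sigma`)

Cover at a sample is the Gaussian-weighted mean of land pixels within
radius `R`, weights `exp(-r²/2σ²)` at pixel centers, water and no-data
pixels excluded from numerator and denominator. Excluding water is not
cosmetic: around a lake it automatically transfers weight beyond the
shoreline, which is where a lake's pollen actually originates.

| parameter | default | unit | rationale |
|---|---|---|---|
| `R` | 50,000 | m | matches the source-area radius assumed by regional pollen–vegetation models, keeping calibrations comparable |
| `sigmas` | 100 / 500 / 10,000 | m | local signal of dense canopies / surface samples (moss, soil) / lake-sized source areas |
| `dense_trigger` | 40 | % | cover above which a forest-context sample may prefer σ = 100 m (kept only when it yields *higher* cover) |
| `small_lake_ha` | 20 | ha | lakes below this use σ = 500 m when surrounded by forest |
| `lake_forest_trigger` | 40 | % | "surrounded by forest" operationalized as water-excluded σ = 500 m cover above this value — no shoreline geometry is available from metadata, so the kernel extraction around the sample is the computable reading |

Distances are great-circle (haversine, authalic radius 6,371,007.2 m);
at ≤ 50 km windows the spherical error is negligible. Pixels enter by
center-in-circle. Lake areas come from sample metadata, not from the
raster: raster-derived areas are resolution-fragile.

The tree-height screen applies only to lake samples (σ = 10 km) inside
the land-class coverage: if the median height within 1σ is zero the
"forest" around them is tall shrubland mis-scored by the cover product
and the sample leaves the analog pool. On grids coarser than σ the
1σ area still contains the sample's own pixel, which is then used.

### Quality control (`qc_modern`, `qc_fossil`)

Rules are conjunctive, so the surviving set does not depend on
evaluation order (duplicate removal, which keeps first occurrences, is
the one order-sensitive step; a "duplicate" is defined as identical
coordinates *and* identical assemblage). The count rule is strict
(> 100 terrestrial grains); `strict_count = FALSE` relaxes it to
≥ 100. The arboreal-pollen consistency rule (AP > 80 % with cover
< 25 %) exempts extensive treeless contexts (tundra, alpine grassland,
desert), where long-distance transport legitimately produces high AP
over open ground. Samples with *missing* location error are retained —
dropping them would depopulate the analog pool for no demonstrated
fault.

### PFT scoring (`taxa_to_pft`)

Biomisation-style affinity: each taxon above the threshold θ (default
0.5 %, standard practice) contributes √(p − θ) to its functional type.
Ambiguous taxa (the *Betula* case — boreal summergreen tree or
arctic–alpine shrub depending on the rest of the flora) are assigned
wholly to the eligible PFT with the larger score computed from the
*other* taxa; exact ties split equally. This makes the assignment
deterministic and context-dependent. One caveat follows from it:
raising θ is guaranteed not to raise any score only while assignments
are stable — a θ-induced flip of an ambiguous taxon can raise the
receiving PFT's score, although the total score is always
non-increasing.

Analog matching operates on the *normalized* score vector: the
squared-chord distance is defined on proportions, and normalization
removes the dependence of raw scores on taxonomic richness.

### The transfer function (`mat`, `predict`, cross-validation)

`k = 8` analogs maximum (selected by leave-one-out RMSEP sweeps;
`loo_k_sweep()` reproduces the selection), squared-chord threshold
`T = 0.3` (sufficient to separate major European vegetation types).
Analog weights are `1/max(d, ε)` with `ε = 1e-9`: inverse-dissimilarity
weighting is the standard MAT convention, and the guard lets an exact
compositional match dominate without dividing by zero. Distance ties
at the k-th rank are all included (then thresholded), so permuting the
calibration set can never change a prediction. The standard error is
`sd(analog covers)/√n` with the n−1 denominator, and is reported as
missing — not zero — when a single analog survives: one analog carries
no spread information. `r²` is the squared Pearson correlation of
predicted versus observed, the transfer-function convention.

Two-fold cross-validation splits the calibration at random halves (odd
sizes: first half larger by one), each half predicting the other,
repeated and pooled; it is unstratified, seeded and reproducible.
h-block cross-validation is deliberately absent from the interface:
land cover is spatially fragmented at short range, and excluding
h-neighborhoods would remove precisely the analogs that carry the
signal.

### Bias correction (`fit_curve`, `apply_curve`)

The correction curve maps raw predictions onto the observed cover
distribution. Construction: per iteration, ten 5-point-wide windows
are placed uniformly at random along the *modeled* axis (the resampling
counters the predominance of low-cover samples; the modeled axis is
the regression abscissa); windows with ≥ 4 pairs contribute their
marginal quartiles, paired by rank; pooled points are reduced to
empirical quantiles at odd percentiles 1, 3, …, 99; a smoothing spline
(smoothness by generalized cross-validation, `spar` overridable) is
fitted to the quantile–quantile pairs; the fitted curve is evaluated on
a dense grid, projected onto the monotone cone by isotonic regression —
a free spline can locally invert, and a calibration must preserve
order — and clamped to [0, 100]. Missing predictions stay missing;
no-analog flags are untouched. The correction is applied mechanically
to all samples regardless of age, composition or location; an
age-dependent correction would smuggle a temporal model into a purely
compositional method.

### Space–time gridding (`timeslice_scheme`, `map_timeslice`, `error_grid`)

49 timeslices, centers every 250 yr from 12,000 to 0 BP. A boundary
age belongs to the *younger* slice (an age of 11,875 falls in the
11,750 slice), and the terminal window is truncated at −60 BP
(AD 2010), spanning 185 yr centered on 0 BP.

Interpolation is a polyharmonic radial-basis spline with kernel
`r² log r` and an affine polynomial part, fitted in scaled
(lon, lat, elev, age) coordinates. The default scaling
(1°, 1°, 1 km, 250 yr all weigh equally) makes one timeslice step and
one vertical kilometer commensurate with one horizontal degree; the
anisotropy of the space–time metric is genuinely open, so the scaling
is exposed in `interpolation_config()`. Each output slice uses sites
within ±2 slices (the temporal dimension earns its keep while bounding
the linear system); the 0 BP slice uses a 3-D spatial fit because its
sampling is one-sided in time. Smoothing is chosen per fit by
generalized cross-validation over a log-spaced grid; `lambda = 0`
interpolates exactly and reproduces affine functions to numerical
precision (both properties are tested). Duplicate coordinates are
averaged; affinely dependent configurations raise a diagnostic error
rather than a silent near-singular solve.

Cover and AP fields are clamped to [0, 100] after evaluation. Cells
farther than 250 km (configurable) from every contributing site are
masked as low-density; water cells of the static land mask are masked
throughout — coastline and ice-sheet evolution is out of scope.

The error grid, produced at a coarser resolution, is the sum of two
terms: the per-sample analog standard error interpolated to the grid,
plus the interpolation's own uncertainty estimated by a delete-one-site
jackknife of the spline prediction at each cell. A resampling estimate
was chosen over any solver-internal variance formula because it is
implementation-independent and directly testable against a brute-force
refit loop. How the two terms should be combined is underdetermined;
simple addition is used, which is conservative.

### Summaries (`regional_series`, `elevation_bands`, `compare_series`, `series_peak`)

Regional means weight cells by cosine(latitude); the reported spread is
inter-cell variability, not reconstruction error. Elevation bands are
200 m wide (below 400 m pooled), capped at 2,800 m throughout, 2,400 m
before 11,000 BP and 2,600 m from 11,000 to 10,000 BP, where high-
altitude sites are too sparse; capped bands are flagged, never silently
dropped. The forest-threshold track reports the *upper edge* of the
highest band whose mean cover exceeds 50 % — an upper-boundary
tracker, matching how timberlines are described. Series comparison
re-bins both series to common 200-yr windows and reports r, mean
absolute difference and regression slope/intercept overall and for the
Early/Mid/Late Holocene.

The timing of a cover maximum is read from a local quadratic (loess)
smooth of the series, not the raw argmax: near a broad mid-Holocene
plateau the series' curvature across neighboring slices is smaller
than the reconstruction noise, making the raw argmax noise-dominated
while the smoothed argmax is stable. `series_peak()` applies the same
estimator to reconstruction and truth.

## What the synthetic generator emulates — and what it does not

`generate_world()` produces a smooth latent cover field (filtered
Gaussian noise whose autocorrelation falls to 1/e at the configured
correlation length, default 60 km), a lake, tree-height and land-class
rasters including a tall-shrubland patch that exercises the height
screen, a DEM, modern samples with realistic context mixtures and
injectable metadata defects, and fossil cores driven by a prescribed
history. The forward model is deliberately the simplest one exhibiting
the structural biases the pipeline must handle: expected arboreal
share = (1−λ)·FC/100 + λ·background with long-distance-transport
fraction λ = 0.15 and a background arboreal share of 0.35, taxa split
within groups by fixed productivity multipliers, multinomial counts at
400 grains. The default history rises from ~55 % of present cover in
the late glacial to a maximum of 1.8× present centered near 7,250 BP —
inside the 8,500–6,000 BP window of maximum Holocene forest — and
declines to present.

What it does **not** emulate: realistic taxonomic richness (8 taxa,
5 PFTs), mechanistic pollen dispersal, climate covariates, spatially
structured defects, age-model error, or the severe analog gaps of real
early-Holocene floras. Consequently, passing tests demonstrate that the
*machinery* is correct — the distances, selections, corrections and
interpolants do what they claim, and the pipeline recovers a known
truth through its full length — but the skill statistics on synthetic
data (LOO r² ≈ 0.9–0.95) say nothing about skill on real data, where
heterogeneous dispersal, taxonomy and metadata noise dominate and
cross-validated r² near 0.5 is the realistic regime.

## Numerical choices and degenerate inputs

* Proportion vectors are validated to sum to 1 within 1e-6; all-zero
  assemblages are errors, not silent zeros.
* Chord distances below 1e-12 are snapped to exact zero so self-matches
  are exact.
* `r²` is reported missing when either margin is constant (it is
  undefined), never coerced to 0 or 1.
* Empty resampling windows are skipped with a log; an all-empty window
  set or a degenerate quantile support is a fitting error.
* Grid I/O uses plain text at full double precision (`%.17g`): round
  trips are bitwise.
* Water and no-data raster codes are distinct reserved values; the
  generator, extraction, masking and QC all distinguish them.

## Problem sizes

The shipped study conditions — a 56 × 84-cell domain at 8 km
resolution, 150 modern samples, 8 fossil sites with 80 samples each,
99-iteration two-fold cross-validation and resampling, 2,000
engineered pairs for the bias-correction contract — were chosen as the
smallest sizes at which every stage operates in its intended regime
(per-slice site counts above the mapping minimum, every 10-point cover
class populated). The full pipeline runs in well under a minute on one
CPU; the bias-correction construction also accepts 999 iterations,
matching the full experimental protocol, at proportional cost.

## Known limitations

* The Gaussian kernel has thin tails; fat-tailed dispersal kernels are
  plausible and unimplemented.
* The bias correction is global; regional or age-resolved corrections
  are rejected by design, at the cost of local over- or
  under-correction.
* The 4-D spline's coordinate scaling is a declared convention, not an
  estimate; reconstructions in strongly anisotropic data regimes should
  revisit it.
* A static land mask ignores coastline and ice-sheet evolution.
* No-analog samples are flagged and excluded, not imputed; sparse
  slices can lose sites below the mapping minimum and are skipped with
  a report.
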