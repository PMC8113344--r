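---
title: "Methods: annual land-cover mapping by probability fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annual land-cover mapping by probability fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annualcover)
```

This vignette is the package's own account of the science it implements:
the model, the assumptions behind each stage, the parameters that matter,
and the design decisions taken where the method leaves room. The worked
numbers shown here are computed by the code as the document notes; the
test suite and `scripts/acceptance.R` recompute all of them.

## Problem and data model

The package targets annual land use/land cover (LULC) mapping of a large,
persistently cloudy study region — the reference use case is
Vietnam-style national mapping — from all available optical and SAR
acquisitions rather than from a single cloud-free mosaic. Its inputs are
analysis-ready, co-registered scenes on one 30 m grid: optical surface
reflectance in six reflective bands plus thermal, with cloud/shadow/nodata
masks, and dual-polarization SAR backscatter (VV/VH, dB). Upstream
preprocessing (atmospheric correction, cloud masking, topographic and
BRDF correction, SAR calibration, resampling) is assumed done; a grid
mismatch between any two inputs is an error, never a silent resample,
because unexamined resampling would contaminate every later distance
computation.

Rasters are stored as multi-page 32-bit-float TIFF with a JSON sidecar
carrying the grid, layer names, and per-layer scale/offset packing (the
`scale_factor`/`add_offset` idiom); masks are four-valued
(valid/cloud/shadow/nodata) and every statistic treats the three nonvalid
codes identically.

## Harmonization

TM/ETM+ reflectance is placed on the OLI scale, and OLI related to MSI,
by band-respective affine transforms `slope * x + intercept` whose
constants ship with the package. Two choices deserve note:

* **No clamping.** Harmonized values are not clipped to [0, 1]: the
  transforms can push saturated pixels slightly past nominal range, and
  clipping would bias composites toward the interior of the range. A
  validity-range warning is emitted instead.
* **Direction of the OLI/MSI pair.** Which way the printed constants map
  is a convention, not a physical fact, so `invert_coefficients()`
  provides the exact algebraic inverse `(1/slope, -intercept/slope)` and
  either direction can be applied; round-tripping is identity to machine
  precision.

## Seasonal compositing

Each year splits into a dry season (April–September) and a wet season
(October–March of the following year, labeled by its starting year).
The season reducers are:

* **Medoid.** Per pixel, the observation minimizing the summed Euclidean
  distance (over the composited bands) to all other valid observations.
  The medoid is always an actual observation, so composites never contain
  between-date mixtures. A single valid observation is its own medoid;
  zero observations give nodata. Exact distance-sum ties — guaranteed in
  two-scene stacks — are broken lexicographically on the band values,
  which makes the result invariant to scene ordering (the tie rule any
  order-dependent choice would violate).
* **Percentile medoids (q = 20, 80).** The phrase "medoid of the q-th
  percentile" is under-specified, so the package defines it as: rank the
  valid observations by NDVI (or by their band mean when NDVI's bands are
  absent), center a window of `ceiling(n/3)` observations on the
  nearest-rank percentile position `round(1 + (n - 1) q / 100)`, and take
  the medoid of the window. The nearest-rank form was chosen because it
  returns actual observations (consistent with the medoid philosophy) and
  because it reproduces the natural oracle on small stacks: on the
  single-band stack {0.1, ..., 0.5}, q = 20 selects 0.2 and q = 80
  selects 0.4. With two or fewer valid observations the plain medoid is
  used. The window fraction is a tunable (`window_fraction`, default
  1/3).
* **Standard deviation.** Population form (divisor n); with fewer than
  two observations the deviation is reported as 0 rather than undefined,
  so constant-valued covariates never produce spurious nodata.
* **SAR seasonal covariates.** Arithmetic means of VV and VH over valid
  observations and `nd_VHVV = (VH - VV)/(VH + VV)` computed **from the
  seasonal means** (the per-scene-then-average alternative is available
  by flag; the default leaves fewer nodata holes). Denominators below
  1e-9 in magnitude give nodata. Ascending and descending orbits are kept
  as separate layers — averaging geometrically different looks would
  discard information the classifier can use.
* **Lee filter.** The classic adaptive speckle filter
  `out = mean + W (in - mean)`, `W = var/(var + noise_var)` with local
  window statistics (default window 5). The noise variance defaults to
  the image-wide mean of local variances, a standard speckle estimate;
  it is a tunable because calibrated products differ.
* **Terrain.** Slope and aspect by Horn's eight-neighbor differences.
  Aspect is degrees clockwise from north of the **down-slope** direction
  in [0, 360), flat cells nodata; the convention is stated because
  several incompatible ones circulate.

## Spectral indices

Seventeen published indices and five band ratios are evaluated exactly as
printed, with two systematic guards: any pixel whose required band is
nodata, or whose denominator magnitude falls below 1e-9, is nodata
(never infinity), and EBBI's square-root radicand must be positive.
Where a formula says a generic "swir", the package uses swir1 (1.6 µm)
except for NBR, which conventionally uses swir2 (2.2 µm); every choice is
overridable per index. Two printed formulas (NDBI and UI) coincide, and
both equal −NBR when given the same swir band; the tests assert these
identities numerically rather than hiding them. Thermal values enter
NDBaI as stored; a scaling hook exists because calibrations differ.

## Training migration

Reference-year training pixels are carried to a target year when their
six-band signatures are "unchanged" under two complementary criteria:
Euclidean distance (brightness-sensitive; threshold 0.05 reflectance
units) and spectral angle (brightness-invariant, shape-sensitive;
threshold 0.95). Signatures default to annual composites (the mean of the
two seasonal medoid stacks), which halves the band noise relative to a
single season; per-season signatures are available.

The 0.95 spectral-angle threshold is genuinely ambiguous: the distance is
an angle (arccos of a cosine similarity), yet 0.95 reads naturally as a
cosine. Both interpretations are implemented —
`sad_interpretation = "angle_radians"` (retain iff angle <= 0.95 rad, the
literal reading, the default) and `"cosine_similarity"` (retain iff
cos(angle) >= 0.95, i.e. angle <= ~0.318 rad) — because guessing intent
silently would be worse than exposing the switch. Comparisons are
inclusive, with a 1e-9 relative epsilon so exact-boundary cases (an ED of
precisely 0.05) are not lost to floating-point round-off. The criteria
combine with AND by default: conservative retention minimizes label
noise, which is the model's entire purpose. A grid-search helper
(`migration_threshold_search()`) supports the trial-and-error threshold
selection the method calls for, but no automatic threshold picking is
imposed.

## The fusion classifier

Each covariate collection (optical-dry, optical-wet, SAR-dry, SAR-wet,
each optionally carrying the ancillary layers) gets its own probability
random forest — 200 trees, `max_features = 8` per split (clamped to the
feature count after pruning), everything else at library defaults, seeded
for determinism. Optional pruning refits after ranking features by
impurity importance and keeps the smallest prefix reaching a cumulative
importance share (default retention 0.95, chosen as a conventional
"keep practically everything informative" level; at least one feature
always survives).

The fusion step is the method's core. Priors are floor-adjusted,
`p' = c p + (1 - c)/N` with c = 0.7 and N the taxonomy size (18 for the
default two-level system; floor `(1 - c)/N = 1/60`), and the posterior is
the product of adjusted priors over contributing collections. The floor
exists because a probability product is annihilated by a single zero: one
noisy collection voting 0 for the true class would otherwise erase three
confident votes. With four unanimous votes the posterior is
`(c + (1-c)/N)^4`, computed by the package as 0.263796 for class k versus
7.7e-8 for every other class; with three votes against one zero the true
class still dominates (6.13e-3, well above any uniformly supported
class). These numbers are asserted in the acceptance suite.

A collection that is nodata at a pixel is **skipped** (contributes no
factor) rather than entered at its floor. The floor's rationale concerns
observed-but-zero priors; flooring absent observations would drag gap
pixels toward uniformity and make I = 2 years incomparable with I = 4
years. The strict alternative (`missing = "floor"`) is provided for
comparison. Pixels with zero contributing collections are nodata.
Posteriors are stored as raw products (argmax is normalization-invariant);
normalization is a flag. Argmax ties resolve to the lowest class id,
deterministically.

## Accuracy assessment

Validation is stratified over **mapped** classes (the confusion matrix's
column totals equal the per-class sample size), with rows = reference and
columns = map, matching the layout of the bundled national tables. The
metric suite: OA; per-class PA and UA; F1 as their harmonic mean on the
0–1 scale; kappa with the usual marginal-product chance agreement; a
binomial 95% half-width for OA; and SEM as the binomial standard error of
UA at the mapped-class sample size. The SEM definition was adopted
because it reproduces every SEM cell of the bundled level-1 table at
n = 1050 to the printed precision — a strong sign it is the definition
the table used. Divisions by zero (empty rows/columns) yield missing
values, never 0. Level-2 results merge to level 1 by summing sibling rows
and columns; counts are conserved and sibling confusion becomes diagonal
agreement, so OA cannot decrease.

One bundled-table caveat: the level-1 aquaculture F1 cell disagrees with
the harmonic mean of its own printed PA (96.2) and UA (94.8), which is
0.9549; the package asserts the recomputed 0.95 for that cell. The
bundled tables' OA uncertainties elsewhere in print are also wider than
the simple binomial half-width at n = 10,500; the package implements the
binomial CI and documents the discrepancy rather than reverse-engineering
an unstated formula.

## Change analysis

Post-classification products: per-pixel counts of consecutive-year label
changes (nodata if any year is nodata); class-area series in km² with the
pixel area taken from the grid (9e-4 km² at 30 m; no geodesic correction,
as maps are assumed in a projected CRS); the annualized net-change rate
`100 (A_t2 - A_t1) / (A_t1 (t2 - t1))` (undefined when A_t1 = 0); a 0–100
min–max rescaling of the **absolute** rates for ranking dynamism (signed
rates are reported alongside; all-equal input rescales to 0); and
transition matrices over jointly-valid pixels whose marginals equal the
area series restricted to the joint mask — an identity the tests check
exactly.

## The synthetic study conditions

The generator emulates exactly the structure the method's assumptions
rely on: per-class six-band mean reflectances drawn to a requested
minimum separation (in units of the band noise SD), additive seasonal
offsets, independent Gaussian band noise, class-wise SAR dB means with
their own noise, patchy rectangular cloud/shadow masks hitting a
requested expected coverage, Voronoi-patch class geometry, and scripted
fractional class conversions between years. The reference conditions used
by the tests and the acceptance script are: six classes at 5 SD
separation (noise SD 0.02 reflectance), 128x128 pixels at 30 m, three
scenes per season and sensor, 30% cloud, 200 training and 200 validation
pixels per class, and a 20% class-1-to-2 conversion planted in the
earlier year. These sizes keep the full series in tens of seconds while
leaving every stage nondegenerate.

What the generator does **not** emulate — spatially correlated and
band-correlated noise (a mixing-matrix option exists), phenology beyond a
constant seasonal offset, mixed pixels, sensor geometry, or
class-dependent cloud cover — bounds what passing tests show: they
demonstrate that the pipeline's machinery is correct and that the method
recovers truth under its own assumptions, not that any particular
real-world accuracy will be achieved. Real-data accuracy depends on class
separability and reference-data quality, which the synthetic conditions
idealize.

## Numerical choices, in one place

* Division guards at |denominator| < 1e-9; EBBI radicand must be > 0.
* Medoid ties: lexicographic on band values (order-invariant); argmax
  ties: lowest class id; percentile-window ties: rank closest to the
  percentile position.
* Threshold comparisons inclusive with 1e-9 relative epsilon.
* Population (divisor-n) standard deviation; < 2 observations give 0.
* Raster packing: per-layer affine to [0, 0.9], missing stored as 1.0;
  round-trip exact to 32-bit-float resolution (tests use 1e-6).
* Seeds: every stochastic stage (spectra, geometry, clouds, sampling,
  forests) takes an explicit seed; the pipeline derives small per-stage
  seeds from one master seed.

## Limitations

The package deliberately excludes upstream preprocessing, reprojection
and resampling, area-weighted (Olofsson-style) accuracy and area
estimation (the bundled tables use naive stratified metrics), probability
calibration beyond the floor adjustment, and deep-learning classifiers.
Regional modeling is supported only through per-region training and
mosaicking by the caller; region geometry is user input.
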