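---
title: "Classifying deforestation and degradation from irregular Landsat time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying deforestation and degradation from irregular Landsat time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltschange)
library(dplyr)
```

## The problem

Tropical forest monitoring must separate three states at the pixel level:
**deforestation** (DEF), where canopy cover falls below the forest-definition
threshold of 20%; **degradation** (DEG), where canopy is damaged but cover
stays at or above 20%; and **stable forest** (NOCH). The classes are defined
purely on the canopy dimension, irrespective of the contiguous area cleared —
field reports rarely support reliable area estimates, while canopy condition
can be verified from plot photos. `ltschange` implements an integrated
pipeline that learns this three-way distinction from two data streams: the
full archive of Landsat-like surface reflectance observations per pixel
(irregularly spaced because of revisit schedules, clouds and scan-line-gap
striping), and geo-tagged disturbance reports filed by local experts, which
accumulate over time and are absorbed into the classifier in phases.

## Spectral bands and preprocessing

Six reflectance bands (B, G, R, NIR, SWIR1, SWIR2) are complemented by eight
derived indices: NDVI, NDMI, NBR, NBR2 and the tasseled-cap brightness,
greenness, wetness and angle. Normalized differences are computed directly;
the tasseled-cap components are fixed linear combinations of the six
reflectance bands using the published surface-reflectance coefficients
shipped in `inst/extdata/tasseled_cap_coefficients.csv` (one coefficient set
for all sensors, since all inputs are surface reflectance). The tasseled-cap
angle is computed as `atan(TCB/TCG)` by default; the more common literature
convention `atan(TCG/TCB)` is available via `tca_convention = "literature"`,
because published definitions disagree and the two differ materially. Zero
denominators and masked observations propagate as invalid.

Cloud masks are consumed, not produced. One mask artifact is handled here:
small clusters of "valid" pixels inside masked regions are usually unmasked
cloud remnants sitting in scan-line gaps, so `apply_sieve()` invalidates
4-connected valid clusters of at most 5 pixels. 4-connectivity is the
conservative choice for sieve filters (diagonal contact does not rescue a
cluster), and the operation is idempotent.

## Temporal metrics

Each pixel/band series contributes six covariates.

**Full-series trend.** `fit_rlm_trend()` fits `value ~ (t − 1999)` with a
Huber M-estimator (tuning constant 1.345, MAD scale, iteratively reweighted
least squares to 1e−8 or 50 iterations — the canonical defaults). Robust
fitting matters because unmasked clouds contaminate real archives; the
intercept is reported at the 1999.0 origin, the start of the usable archive.
On noiseless input the M-estimate equals least squares, which the tests
assert to 1e−8; the implementation short-circuits to the LS solution when
the residual scale is numerically zero, where a MAD estimate would
degenerate.

**Season-trend model.** Within a segment the series is modelled as

$$y(t) = \alpha + \beta\,(t - t_0) + \gamma \sin(2\pi t + \delta),$$

fit robustly via the linearisation $a\sin 2\pi t + b\cos 2\pi t$ with
$\gamma = \sqrt{a^2+b^2}$, $\delta = \mathrm{atan2}(b, a)$. Time is decimal
years (`year + day_of_year/365.25`), which makes the annual cycle exactly
`sin(2πt + δ)` — a deliberate interpretation of the "365-day frequency"
phrasing common in this literature, since only an annual-period harmonic is
dimensionally coherent. A single first-order harmonic is used; higher orders
chase noise at these observation densities. The fit requires ≥ 8
observations spanning ≥ 1 year (below that, the amplitude is not
identifiable and the band's metrics are set to missing). The whole-series
robust trend is purely linear, without a seasonal term: it is a
low-frequency descriptor, and the seasonal signal is captured by the
per-segment fits.

**Single-break detection.** Land-use conversion in smallholder landscapes is
assumed to happen at most once per 16-year window, so `detect_single_break()`
compares a no-break season-trend fit against the best one-break pair by BIC:
`n·ln(RSS/n) + k·ln(n)` with k = 4 (no break) versus k = 9 (two segment
models plus the break position). Candidate breaks keep every segment at
least `max(⌈0.15 n⌉, 8)` observations — 15% is the standard minimum-segment
default of regression-based break search, and 8 is the parameter count plus
slack. The scan uses least-squares RSS (the classical break-search
criterion); accepted segments are then refit robustly, mirroring the
standard chaining of break detection into robust segment fits. BIC ties
resolve to no break (parsimony), and when both RSS terms are exactly zero
(noiseless data) the simpler model wins. Break *timing* is deliberately not
an output — only presence/absence and the induced segmentation; the metrics
are state descriptors, not event dates.

**The metric vector.** Per band: `rlm_intercept`, `rlm_slope`, `gamma1`,
`gamma2`, `beta1`, `beta2`, with segment-2 values duplicating segment 1 when
no break was found, so the vector length is constant (84 for the full
14-band set).

## The change classifier

`train_change_model()` fits a random forest (default 7000 trees, matching
the full-model configuration; the out-of-bag error stabilises far earlier,
so repeated experiments here use 300–500 trees) on the metric columns.
Accuracy is always quoted as OOB error — each sample judged only by trees
whose bootstrap excluded it — and class probabilities are vote fractions,
which sum to 1 exactly. Rows with missing covariates are dropped with a
message before training; forests require complete rows.

**Band importance.** Within-forest importance measures vary run to run and
are hard to interpret under strongly correlated covariates (conditional
permutation importance being computationally prohibitive at this covariate
count), so importance is scored by repeated *single-band* models:
iteration i fits one forest per band on that band's six metrics alone,
accuracies (1 − OOB error, overall and per class) are ranked across bands
(bottom = 1, top = n), and the score is the averaged normalized rank

$$S_{j,\Delta} = \frac{1}{N}\sum_{i=1}^{N} \frac{x_{i,j} - 1}{n - 1} \in [0, 1].$$

Ranking ties break by canonical band order — deterministic and
seed-independent. Within an iteration, every band's forest uses the same
seed, so bands differ only in covariates, not bootstrap luck. The default
N = 1000 iterations at 500 trees per single-band forest keeps the scoring
affordable; tree count is configurable. `importance_scores()` exposes the
scoring formula directly on a rank matrix, which is also how the analytic
extremes (top rank always → S = 1, bottom always → S = 0) are verified.

**Phased updating.** `iterative_update()` formalises the absorption of a
continuous report stream: train on period A, validate on period B by
predicting class probabilities for B's locations grouped by reference label;
then train on A ∪ B and validate on period C. Validation predictions use the
full forest (B and C locations are disjoint from the training rows, so no
OOB correction is needed). `plot_phase_probabilities()` renders the grouped
distributions as boxplots.

**Mapping.** Wall-to-wall prediction cannot afford break detection on every
pixel for all 14 bands, so mapping uses a reduced model:
`reduced_covariate_set()` — all six metrics of SWIR2 and TCW plus the robust
intercept and slope of G (14 columns), the subset that importance scoring
selects on both the field study's data and the synthetic populations
(SWIR bands respond most strongly to canopy-opening in moist forest, and
the green-band trend separates stable forest). `map_change()` computes the
schema's metrics per forest pixel and predicts vote fractions; non-forest
pixels and pixels with too few valid observations are nodata rather than
guessed, and output is identical under any pixel processing order. The
baseline forest mask thresholds NDVI (default 0.6) at each pixel's earliest
clear acquisition from the baseline onwards; a classified external mask can
be substituted, since the mask's provenance is an input, not a product.

## The synthetic-data generator

The field data behind the original analysis are not deposited, so the
package is driven by a generator that emulates the statistical structure the
method assumes, with known truth:

* **Trajectories** follow the piecewise season-trend model above with at
  most one break. DEF pixels take an abrupt persistent step (NIR down ~0.13,
  SWIR2 up ~0.07, visible up slightly — the direction canopy opening moves
  surface reflectance in moist forest, crossing the 20%-cover analogue);
  DEG pixels take either a partial step (default 40% of the DEF magnitude)
  or a gradual trend of the same sign with no break; NOCH pixels are stable
  seasonal; NONFOREST pixels hold low-NDVI cropland-like reflectance. Base
  levels are jittered log-normally (5%) so classes are populations.
* **Sampling** lays acquisitions on a 16-day revisit over 1999–2015,
  removes 30% at random (clouds and gap striping), adds Gaussian noise
  (default sd 0.01 reflectance), and shifts 5% of surviving observations by
  a one-sided outlier (default magnitude 0.15; negative in NIR, positive in
  visible/SWIR — the signature of unmasked cloud that robust fitting is
  meant to resist). All bands of a pixel share the break time, the cloud
  pattern and the per-date validity mask.
* **Reports** are placed on disturbed pixels (plus stable-forest
  supplements, default one third) with purposive spatial sampling modelled
  as a logistic accessibility gradient across scene columns, because real
  community monitoring is not probabilistic sampling; uniform sampling is a
  flag. Form attributes (canopy cover, disturbance evidence, forest status)
  are drawn consistently with the label, timestamps follow each pixel's
  break after a short reporting delay, and a configurable label-noise rate
  flips labels. Phase boundaries partition the stream into periods A/B/C.

What the generator does **not** emulate: radiative-transfer realism,
spatial autocorrelation beyond the accessibility gradient, multi-break
histories, sensor-to-sensor radiometric differences, and co-registration
error. Passing tests therefore demonstrate that the pipeline recovers the
structure it models — piecewise harmonic trajectories under realistic
gap/noise/outlier regimes — not that it attains any particular accuracy on
real archives, where class overlap is far stronger (the original study's
OOB errors of ~29% reflect that overlap; the clean synthetic populations
here separate almost perfectly by design).

## Simulation conditions used in the tests

Chosen once as representative desk-scale conditions: parameter-recovery
experiments use 200 replicates of ~250-observation series (16-day revisit,
30% dropout, 16-year span) at noise sd 0.02 with 5% outliers; break
detection uses 100 replicates with a 5σ level drop (power and location) and
100 stable series (false positives); classifier checks use 300 pixels per
class with the reduced three-band metric set; phased updating uses 20
seeded 16×16-pixel scenes with 150 reports split at 2007.5/2011.5; mapping
uses a 20×20 scene at 60 acquisitions. Scene experiments use 40–60 evenly
spaced dates — enough for ~28–42 valid observations per pixel after
dropout, comfortably above the 2×8-observation minimum the break scan
needs.

## Numerical choices and degenerate inputs

* Robust fits short-circuit to least squares when the LS residual scale is
  below 1e−10 of the response scale (noiseless inputs).
* `detect_single_break()` on a series shorter than twice the minimum
  segment returns a degenerate no-break result with `bic1` absent rather
  than erroring: mapping should skip such pixels, not crash.
* Phase `delta` is reported in (−π, π]; amplitude is non-negative by
  construction.
* Zero-denominator indices and masked pixels are `NA` everywhere; a pixel
  with zero valid observations yields an empty series and, downstream,
  missing metrics and a nodata map pixel.
* The 20% canopy threshold is compared strictly (`< 20` → DEF), so exactly
  20% cover remains degradation, consistent with "reduced to below" the
  forest definition.

## Known limitations

Single-break segmentation cannot represent disturbance–recovery cycles
(shifting cultivation); the generator and classifier share the same
trajectory family, which is the point of a self-consistency harness but
flatters accuracy relative to real data; the forest mask is a simple NDVI
threshold unless an external mask is supplied; and no map-accuracy
assessment against independent reference data is included.

## A worked example

```{r example, eval = FALSE}
scene <- generate_scene(20, 20, n_dates = 60,
                        sampling = sampling_model(seed = 11))
training <- simulate_training_set(100, n_dates = 60, seed = 21)
model <- train_change_model(reduce_covariates(training, reduced_covariate_set()),
                            n_trees = 500, seed = 3)
glance(model)
mask <- build_forest_mask(scene)
maps <- map_change(scene, model, mask)
mean(maps$modal[!maps$nodata] == scene$truth_class[!maps$nodata])
plot_probability_maps(maps)
```
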