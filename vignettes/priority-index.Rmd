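---
title: "Fusing occurrence and abundance models into a priority protection index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing occurrence and abundance models into a priority protection index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmPriority)
```

## The model

`sdmPriority` treats conservation prioritization as the fusion of two
predictive surfaces over a common 30 m raster lattice.

The **occurrence model** is a random-forest classifier contrasting
presence points with random pseudo-absences drawn uniformly from the
study area. Its per-pixel output is the *relative index of occurrence*
(RIO): the fraction of trees voting for the presence class, an index in
[0, 1] rather than a calibrated probability. Presence data are typically
two orders of magnitude scarcer than background points (94 flock sites
against 10,000 pseudo-absences in the motivating use case), so the
classifier is fitted with balanced class weights

$$w_c = \frac{N}{2\,N_c},$$

which up-weight the minority presence class exactly enough that both
classes contribute equally in expectation.

The **abundance model** is a random-forest regressor of flock counts at
the presence sites on a predictor subset chosen by greedy forward
selection (see *Numerical choices*). Raw regression-forest output
systematically compresses the count range — it under-predicts large
flocks and over-predicts small ones — so a linear calibration

$$\text{adjusted} = A \times \text{predicted} + B$$

is fitted by ordinary least squares of observed counts on out-of-bag
predicted counts, then applied pixel-wise to the whole predicted surface
(clipped below at zero: counts cannot be negative).

The two surfaces are fused into the **priority protection index**

$$PI = \frac{RIO \times RA}{\max(RIO \times RA)},$$

with RA the adjusted abundance and the maximum taken over valid pixels.
PI inherits the strengths of both models: a pixel scores high only if
the species is both likely to occur *and* expected in numbers there. The
index is invariant to positive rescaling of RA — only relative abundance
matters — monotone in the product, and attains 1 at the product's argmax.
When every product is zero the index is an undefined 0/0; `computePI`
raises an error rather than returning an all-zero map that would
silently read as "no priority anywhere".

Assumptions worth keeping in mind: pseudo-absences are *background*, not
true absences, so RIO is a relative ranking; occurrence and abundance are
modelled independently (no shared error structure); and PI deliberately
applies no weighting by biotic or socioeconomic value — it is a purely
biological prioritization.

## The predictor stack

Eleven aligned layers (`predictorNames()`):

| layer | unit | construction |
|---|---|---|
| `dist_*` (8 feature classes) | m | exact Euclidean distance transform, center to center |
| `farmland_area` | km² | area of the 4-connected farmland patch containing the pixel |
| `mnndvi`, `maxndvi` | – | pixel-wise mean / max over the monthly NDVI stack |

Distance layers are computed with `EBImage::distmap` (an exact Euclidean
distance transform, verified against a brute-force oracle in the test
suite), patch labelling with `EBImage::bwlabel` (4-connected). Distances
are measured between pixel centers, matching the behavior of the common
GIS raster distance tools and keeping the operation oracle-testable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nTrees` | 1000 | trees per forest; the OOB scores need enough trees that every training point is out of bag somewhere (the fit errors otherwise) |
| `balanced` | TRUE | class weights $N/(2N_c)$ in the occurrence forest |
| `nBackground` | 10000 | pseudo-absences, drawn without replacement from valid pixels |
| `trainFraction` | 0.8 | abundance train/test split, `round(0.8 n)` training rows |
| `tol` (stepwise) | 1e-3 | minimum OOB-R² improvement to keep adding a predictor |
| `idwParams(power, k)` | 2, 12 | IDW exponent and neighbourhood; common GIS defaults, exposed because the right smoothing radius depends on sampling density |
| `nBins` (relation curve) | 10 | equal-width RIO bins on [0, 1] |

## The synthetic landscape and virtual species

Field censuses of the kind this pipeline targets are rarely shareable,
so the generator provides a study system with known truth:

* **Extent**: defaults emulate a ~2,190 km² farmland plain at 30 m
  pixels (1560 × 1560); examples and tests use 100 × 100 (3 km × 3 km)
  windows with feature densities scaled accordingly.
* **Features**: pools and residential areas as random discs, roads,
  rivers and ditches as random one-pixel polylines crossing the extent;
  farmland as a thresholded smoothed Gaussian field covering a
  configurable fraction (default 0.764) of the study area.
* **NDVI**: monthly fields sharing a persistent base pattern (weight
  0.7) plus month-specific noise, mimicking the way winter vegetation
  structure persists across a season; values centred near 0.14 with
  landscape-scale standard deviation ≈ 0.04, clipped to [−1, 1].
* **Virtual species**: occurrence probability is a product of
  per-predictor *plateau kernels* — 1 inside a preference interval
  `[low, high]`, a small `penalty` outside — rescaled to maximum 1;
  expected abundance is `lambdaMax` times an analogous product over a
  (possibly different) predictor subset. Counts at presence sites are
  negative binomial with mean λ and variance `dispersion · λ`, truncated
  to ≥ 1, producing many small flocks and rare large ones. The
  dispersion default (8) is a realism choice for flocking farmland
  birds, not an inference about any particular species.
* **Seeds**: all randomness flows from one master seed through
  `childSeed(seed, stream)`, a documented linear-congruential splitter;
  every generator and fit is bit-reproducible given its seed.

`demoResponseConfig()` is the documented strong-signal configuration
used across the examples and validation suite: occurrence dominated by
mean winter NDVI ≥ 0.20 (≈ 12 % of the landscape) with a mild secondary
preference for intermediate distance to residential areas; abundance
driven by a disjoint pair (distance band to the national road, avoidance
of pool vicinity). The deliberate divergence between the two responses
is what makes the PI fusion informative rather than redundant.

What the generator does *not* emulate: realistic road-network topology,
crop-rotation dynamics, spatially correlated observation error, detection
failure, and landscape configuration effects beyond first-order distance
and area predictors. Passing recovery tests therefore demonstrate that
the pipeline recovers structure *when its assumptions hold*, not that it
is robust to every property of real census data.

## Numerical choices

* **Pixel convention**: origin at the top-left corner, x east, y south,
  half-open pixels — a point on a shared edge belongs to the pixel
  right/below. One unambiguous containment rule, tested against index
  arithmetic.
* **Stepwise criterion**: greedy forward selection maximizing the
  *explained-variance* OOB R² (1 − SSE/SST on out-of-bag predictions).
  This form goes negative when a candidate predicts worse than the mean,
  so pure-noise candidates cannot clear the `tol` threshold — the
  sign-blind squared-correlation form would admit them. Ties break by
  candidate order; selection is deterministic given the seed.
* **Reported R²**: the observed-vs-predicted R² reported by the pipeline
  is the squared Pearson correlation (the usual calibration-scatter
  usage); `rSquared(method = "ss")` exposes the explained-variance form.
* **Adjustment data**: the calibration regresses observed counts on the
  final model's *out-of-bag* predictions. Resubstitution predictions
  would inflate the apparent fit quality; OOB keeps the calibration and
  the validation framing consistent.
* **Exact pseudo-absence counts**: exactly `n` distinct pixels are
  drawn ("approximately n" is not testable); presence pixels are not
  excluded, mirroring plain random background sampling — the collision
  probability at study scale is negligible.
* **NDVI nodata**: summaries use the months available at a pixel; a
  pixel is nodata only when every month is. Non-farmland pixels carry
  farmland-area 0, not nodata, so background points off farmland remain
  usable.
* **Partial dependence**: the standard substitution average (mean
  prediction over training rows with the variable pinned to each grid
  value) — definitionally oracle-testable.
* **PI normalization** uses the unsmoothed pixel products; IDW smoothing
  is cosmetic, applied only to surfaces bound for maps, and both
  smoothed and unsmoothed surfaces are exported.
* **Raster interchange** uses plain-text Esri ASCII grids written at
  full double precision (lossless round trips), with a JSON sidecar for
  provenance (seeds, settings, the PI normalization constant).

## Validation problem sizes

The test suite validates oracle equivalence of every core operation on
hundreds of random small instances, the Eq.-style properties of PI
exhaustively on random grids, and parameter recovery on twenty seeded
100 × 100 landscapes (94 presence sites, 1,000 pseudo-absences, 500
trees): mean out-of-bag ROC ≥ 0.9, the true occurrence driver ranked
first in ≥ 18/20 runs, known calibration coefficients recovered within
2 %, and the adjusted abundance surface rank-correlated > 0.6 with the
true expected-count surface in every run. The end-to-end pipeline runs
on a 200 × 200 landscape with the full 10,000 pseudo-absences and
1,000-tree forests. These sizes were chosen to exercise every code path
at full statistical strength while keeping the default suite fast on a
single CPU.

## Known limitations

* RIO is a vote fraction, not a calibrated probability; thresholding it
  into range maps is out of scope.
* The abundance model shares the weaknesses of regression forests at the
  extremes — the linear adjustment recenters but cannot fully undo the
  compression of rare high counts. Binned-abundance classification would
  be a natural extension.
* No spatial cross-validation: out-of-bag validation is blind to spatial
  autocorrelation between nearby points.
* Reprojection, vector-geometry distances and multi-scale analysis are
  out of scope; all inputs must share one grid.
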