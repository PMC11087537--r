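---
title: "Design-based accuracy assessment and consensus analysis of cropland maps"
author: "cropconsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based accuracy assessment and consensus analysis of cropland maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropconsensus)
```

## The problem

Binary crop/non-crop maps derived from satellite data disagree substantially,
and their published accuracies are rarely comparable: they were estimated
with different reference data, different sampling designs, and sometimes no
design at all. This package implements the two halves of a rigorous
intercomparison: (i) *design-based* accuracy estimation, in which each map is
evaluated against a probability sample of interpreter-labeled reference
points and every estimate is weighted by the map's own class areas, and
(ii) *consensus analytics*, which quantify where and how much a set of maps
agree, independent of any reference data.

## The estimation model

### Population error matrix

Let the sample confusion matrix be

$$C = \begin{pmatrix} TN & FN \\ FP & TP \end{pmatrix},$$

with rows indexing the *map* class (row 1 = non-crop, row 2 = crop) and
columns the *reference* class. Let $A = (n_{neg}, n_{pos})$ be the number of
pixels the map assigns to each class, $n$ their sum, and $W = A/n$ the area
weights. Sample counts alone over-represent whichever class was over-sampled;
re-expressing them as estimated *proportions of mapped area*,

$$p_{ij} = W_i \, \frac{C_{ij}}{C_{i\bullet}},$$

yields the population error matrix $E$, whose row sums equal $W$ exactly and
whose entries sum to 1. All metrics derive from $E$:
overall accuracy $OA = \sum_i p_{ii}$, user's accuracy (precision)
$P_i = p_{ii}/p_{i\bullet}$, producer's accuracy (recall)
$R_j = p_{jj}/p_{\bullet j}$, and $F_1 = 2PR/(P+R)$ for the crop class.

A note on normalization: the row-sum denominator $C_{i\bullet}$ is the only
choice consistent with the variance estimators below and with the identity
$\mathrm{rowSums}(E) = W$, and it is what `populationMatrix()` implements.
It also makes each row of $E$ interpretable as the map class's area share
split by the *sample-estimated* conditional distribution of the reference
class — exactly the quantity a stratified-by-map-class design estimates.

### Variance estimators

Each stratum (map class) contributes a binomial-style term:

$$V(OA) = \sum_i \frac{W_i^2 P_i (1-P_i)}{C_{i\bullet} - 1}, \qquad
V(P_i) = \frac{W_i^2 P_i (1-P_i)}{C_{i\bullet} - 1},$$

$$V(R_j) = \frac{1}{\hat N_{\bullet j}^2}\Big[
  \frac{A_j^2 (1-R_j)^2 P_j (1-P_j)}{C_{j\bullet}-1}
  + R_j^2 \sum_{i \ne j} A_i^2
    \frac{C_{ij}}{C_{i\bullet}}\Big(1-\frac{C_{ij}}{C_{i\bullet}}\Big)
    \Big/ (C_{i\bullet}-1) \Big],$$

with $\hat N_{\bullet j} = \sum_i (A_i / C_{i\bullet}) C_{ij}$ the estimated
pixel total of reference class $j$. Reported uncertainty is always
$\sigma = \sqrt{V}$.

The $W_i^2$ factor in $V(P_i)$ is kept as the default (`varianceMode =
"printed"`) for fidelity to the published formula set, but note that the
sampling variance of the *conditional* proportion $P_i$ is the binomial form
without that factor; `varianceMode = "standard"` provides it. The package's
own recovery tests use the standard form when asking whether an estimated
UA sits within sampling error of its known true value, because the
$W^2$-scaled quantity is systematically narrower than the estimator's actual
spread. Degenerate cases are handled by convention rather than error where a
published report does the same: a class that is never mapped
($p_{i\bullet}=0$) or never observed in the reference ($p_{\bullet j}=0$)
has its metric and SE reported as 0, and a weighted stratum with fewer than
two samples reports SE 0 with a warning (the variance is undefined).

### F1 error propagation

$F_1 = X/Y$ with $X = 2PR$ and $Y = P+R$ share their inputs, so their
uncertainties are dependent and relative errors add rather than combining in
quadrature:

$$\Delta F_1 = \frac{2(R\,\Delta P + P\,\Delta R)}{P+R}
             + \frac{2PR(\Delta P + \Delta R)}{(P+R)^2}.$$

This is a worst-case (perfect positive dependence) linear propagation; it is
conservative relative to a delta-method variance with estimated covariance,
and is what `f1WithError()` implements, returning 0 ± 0 when $P+R=0$.

## Sampling and response design

`sampleUniform()` draws points uniformly over a polygon by rejection from
its bounding box. `sampleStratified()` implements equal-allocation stratified
sampling over a covariate raster with left-open/right-closed intervals
$(a, b]$ — the convention in which an NDVI stratification like
$(-1,0.13], (0.13,0.2], (0.2,0.3], (0.3,1]$ is written — assigning each
sampled cell a uniform position within it so the point's covariate value is
exactly the cell's. A stratum with no eligible pixels yields zero points and
a warning rather than an error, since the remaining strata are still usable.

The response design assigns each point to $L \ge 2$ interpreters;
`consensusFilter()` retains exactly the unanimous points and sets their final
label. With independent per-interpreter error $\varepsilon$, retention is
$(1-\varepsilon)^L + \varepsilon^L$ and the residual error among retained
points is $\varepsilon^L / ((1-\varepsilon)^L + \varepsilon^L)$ — with
$\varepsilon = 0.1, L = 2$: 82% retained, 1.2% of those mislabeled. The same
estimator is applied to uniformly and stratified-sampled datasets alike; the
validity window of a dataset is carried as metadata only.

## Consensus and ensembles

`consensusRaster()` counts crop votes per pixel across $K$ maps on one grid.
A pixel where *any* constituent map is nodata is excluded entirely —
otherwise a "3 of 7" pixel and a "3 of 11" pixel would be incomparable.
`consensusSummary()` reports the percentages of pixels with unanimous crop,
unanimous non-crop, their sum, and "split" pixels whose vote count is in
$\{\lfloor K/2 \rfloor, \lceil K/2 \rceil\}$ (e.g. 5 or 6 of 11). The
majority-vote ensemble calls crop only on a strict majority (votes $> K/2$),
so an even split is non-crop. Pairwise agreement between two maps is the
fraction of mutually valid pixels on which they agree; the diagonal of the
agreement matrix is fixed at 0 by convention, maps are ordered fine-to-coarse
by native resolution (ties by name), and per-row ranks break ties toward the
lower column index so ranks are deterministic and order-independent.

## The synthetic generator

The generator exists so that every estimator in the package can be checked
against known truth. What it emulates, and its defaults:

* **Truth landscape** — white noise smoothed by a separable Gaussian kernel
  (default scale 5 px, comparable to field-block sizes of a few hundred
  meters at 10 m/px) and thresholded at the empirical quantile that realizes
  the target crop fraction (default 0.3, in the range of the crop shares of
  the agricultural study regions the design mimics). The quantile threshold
  hits the target fraction to within one pixel; patches are spatially
  autocorrelated rather than i.i.d.
* **Product maps** — the truth aggregated to each product's native
  resolution by majority vote of covered pixels (ties to non-crop, the
  dominant-class semantics of coarse products), then degraded by independent
  per-pixel flips: omission $o$ on crop, commission $c$ on non-crop. True
  accuracies are then known in closed form: $PA = 1-o$,
  $UA = (1-o)f / ((1-o)f + c(1-f))$.
* **Labels** — each interpreter flips the true label independently with the
  label-noise rate (default 0.1; interpreter disagreement rates are not
  empirically anchored, so this is a free parameter chosen at a plausible
  photo-interpretation error level and exposed in the scenario).
* **NDVI** — each pixel follows a 23-step (16-day cadence) annual sinusoid
  with class-specific baseline and amplitude (crop 0.35 ± 0.35, non-crop
  0.30 ± 0.08, noise SD 0.05), clamped to $[-1, 1]$.

Every generator is a pure function of its inputs and a seed (the RNG state
is saved and restored around each call), so identical scenarios give
bit-identical outputs — the basis of the pipeline's byte-reproducibility.

What the generator does *not* emulate — spatially correlated classification
error, registration error between maps, mixed pixels at field boundaries,
interpreter biases correlated with land cover, or realistic phenology —
bounds what passing tests show: they validate the estimators and the
pipeline's bookkeeping under the stated error model, not any claim about
real map products.

## Numerical and design choices

* **Cell convention.** Pixel (1,1) is the upper-left cell; a cell's extent
  is half-open, $[\mathrm{left}, \mathrm{right}) \times (\mathrm{top},
  \mathrm{bottom}]$, so every point belongs to exactly one cell and a point
  on a shared edge is assigned deterministically. Value extraction at a
  point is containing-cell lookup; categorical resampling is
  nearest-neighbor by target-cell-center lookup (averaging class codes is
  meaningless), and exactly nested grids resample exactly.
* **Clipping and nodata.** A pixel is retained iff its center is inside the
  boundary (centers on the edge count as inside — a measure-zero set needing
  a deterministic rule); retained values are unchanged bit for bit. Nodata
  pixels are excluded from every count and statistic.
* **Binarization.** Threshold rules are strict (`> cutoff`) by default;
  fraction-range rules are inclusive at both ends (the plain reading of a
  range "from 5–95%"); mode composites break frequency ties toward the
  lowest class code.
* **Reporting.** All computation is in full precision; displayed tables
  round to 2 decimals ("value ± SE"), and full-precision columns accompany
  display columns in written CSVs.
* **Problem sizes.** The validation suite uses grids from 4×4 (hand-checked
  oracles) up to 200×200, reference samples up to 2,000 points, 2,000
  Monte-Carlo replicates for the SE-calibration check, and 200 randomized
  trials per brute-force oracle comparison — sizes at which closed-form
  tolerances (3 Monte-Carlo SEs; 10% relative error on SE calibration) are
  sharp while the full suite runs in well under a minute per module.

## File formats

Rasters are stored as Esri ASCII grids (plain-text, georeferenced by a
six-line header) with a JSON sidecar carrying product metadata; points as
GeoJSON FeatureCollections and flat CSV; matrices and tables as CSV;
scenarios as flat `key = value` configs echoed verbatim into each run's
manifest. Text formats keep every artifact inspectable, diffable, and
reproducible from `(config, seed)` alone.

## Known limitations

* Binary crop/non-crop only; the multi-class generalization of the
  estimators is out of scope.
* The same estimator is applied to all sampling designs; stratum-specific
  inclusion probabilities for stratified designs are not used in estimation.
* The F1 error is a dependence-conservative bound, not a delta-method SE.
* No significance tests accompany Pearson correlations (small map samples);
  undefined correlations (zero variance) are flagged, never zeroed.
* No cartographic output; matrices and rasters are data products, and
  plotting is left to the user.
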