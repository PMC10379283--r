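---
title: "Mapping observed heterozygosity from anthropogenic predictors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping observed heterozygosity from anthropogenic predictors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmap)
```

## The model and its assumptions

`hetmap` treats compiled per-population estimates of observed heterozygosity
(Ho, a proportion in [0, 1]) as a point-referenced response and five gridded
anthropogenic predictors — GDP per capita, human population density, the
gridded relative deprivation index, and travel times to the nearest city and
port — as covariate surfaces. The scientific question is associative, not
causal: which of these predictors best describes the spatial variation of Ho
for a commensal species, and where on the globe can a fitted model be
projected without extrapolating?

The assumptions baked into the pipeline are worth stating explicitly:

* **Comparability of Ho across studies.** Ho is the only diversity metric
  available from every compiled source, and only nuclear markers
  (microsatellites, SNPs, RADseq) are admitted, because mitochondrial
  heterozygosity is not on the same scale. This is enforced at parse time:
  a row with a mitochondrial marker is rejected, not converted.
* **Complete cases only.** A locality missing any predictor value is dropped
  and counted; no pixel is ever imputed. This trades sample size for
  reproducibility and avoids fabricating covariate values.
* **No spatial-autocorrelation correction.** The compiled localities are too
  few and too unevenly distributed for spatial thinning or autocorrelation
  modelling; results are descriptive at the macro scale, and nothing in the
  regression accounts for spatial dependence between nearby localities.
* **Nonlinear, interaction-friendly regression.** A random forest makes no
  functional-form assumption and cannot predict outside the range of the
  training response — an asset here, since predicted Ho stays in the
  observed [min, max] automatically.

## Stages and the parameters that matter

### Raster harmonization

All layers are resampled to a common grid by nearest-neighbour assignment
(`resample_nearest()`), the appropriate choice when layers mix counts,
indices and travel times whose values must not be blended. The working
resolution defaults to 2.5 arcminutes (about 5 km at the equator). Two
numerical conventions are fixed and tested rather than left to chance:

* cell membership for point extraction uses half-open pixel intervals
  [left, right) × (top, bottom], with longitudes exactly on the
  antimeridian wrapped to −180;
* a nearest-neighbour tie (a target center equidistant between source
  centers) resolves to the smaller row, then the smaller column index.

A consequence of the half-open rule is that a point exactly on the grid's
northern edge falls outside the grid; with real coordinates this is a
measure-zero event.

### Description

The correlation screen (`correlation_screen()`) reports the Pearson r of
each predictor against Ho with its two-sided t-test p-value; it is a
multicollinearity check, not a variable-selection step — nothing is dropped.
PCA (`run_pca()`) standardizes all active variables; Ho is active by
default, since the localities are inspected "according to" Ho and the
predictors together, and `include_ho = FALSE` demotes it when a
predictors-only ordination is wanted. Clustering on component scores
(`hcpc()`) retains components explaining at least 1/p of the variance (the
Kaiser rule on standardized data), applies Ward linkage on Euclidean
distances, and — when k is not supplied — picks the partition in 2..10 with
the largest relative drop of within-cluster inertia relative to one fewer
cluster. The island/mainland contrast uses a two-sided Wilcoxon rank-sum
test: exact enumeration when both groups have at most 10 records and no
ties, otherwise the normal approximation with tie correction. When every
observation is tied the null variance is zero and the p-value is defined
as 1.

### Random-forest regression

`rf_config()` fixes the knobs:

| parameter | default | unit | rationale |
|---|---|---|---|
| `tree_grid` | 10, 25, 50, 100, 250, 500, 1000, 2500, 5000, 10000 | trees | log-spaced cover of the searched range 10–10,000 |
| `variables_per_split` | 2 | predictors | ⌊√5⌋, the standard regression-forest default |
| `min_node_size` | 5 | records | standard regression default |
| `seed` | 1 | — | recorded in every fit and report |

The grid search (`grid_search_trees()`) refits the forest at every candidate
size with the same seed and keeps the fit with the minimum out-of-bag RMSE,
ties going to the smaller forest; the whole trace is kept for the run
report. Validation is leave-one-out (`jackknife_validate()`): with fewer
than a hundred records per species a held-out split would be wasteful, so
each record is predicted by a forest trained on the other n − 1, reusing the
grid-search winner's tree count (re-searching inside every jackknife refit
would multiply cost for no obvious benefit). The refit for record i uses
seed `base + i`; because that derivation is positional, reordering records
changes individual refit seeds, so order-invariance of the jackknife holds
statistically (same accuracy, same record-to-prediction pairing) rather than
bit-for-bit.

Variable importance is the impurity (variance-reduction) importance summed
over all splits — the regression-forest analogue of the Gini index — and is
reported max-normalized (`normalize_importance()`), so the most important
predictor scores exactly 1 and the other values are fractions of it. This
normalization is the only reading consistent with per-species importance
columns that each peak at exactly 1. A constant response takes a defined
degenerate path: OOB RMSE 0, all raw importances 0, and normalization
refuses the all-zero vector.

### MESS and the validity mask

The MESS implementation is from scratch and oracle-tested. For one
predictor with reference values r₁…rₙ and query value p, let
f = 100·#{rᵢ < p}/n (strictly-less counting); the similarity is the
piecewise score given in the README, and the MESS of a cell is the minimum
across predictors. The formula is the canonical published definition; the
suite checks it against an independent brute-force double loop on a hundred
randomized instances at 1e−9, plus unimodality and
duplicated-reference-point properties. One subtlety of strict counting: a
query exactly at a variable's median reaches similarity 100 only for even
reference counts (odd n gives f just under 50); the oracle tests pin this
behaviour down.

The default mask keeps cells whose MESS strictly exceeds the **median of
the strictly positive MESS values** (even counts use the midpoint of the two
central order statistics; cells equal to the threshold are excluded). This
rule is aggressive — it discards roughly the lower half of even the
non-extrapolated area — but it is the rule the pipeline is built around, and
its intent is to keep only projections made under conditions well inside
the training envelope. `validity_mask(rule = "nonnegative")` exposes the
conventional milder mask (keep all non-extrapolated cells) without changing
the default.

## The synthetic-data generator

`synthetic_scenario()` is first-class, tested code, not a fixture: it
defines the conditions under which the pipeline's statistical behaviour is
demonstrated. Each predictor field is a seeded sum of 10 Gaussian bumps with
random centers and widths 0.04–0.15 of the extent, standardized over valid
cells — smooth like real socioeconomic surfaces (so nearest-neighbour
resampling and MESS behave realistically), with widths small enough that
independently drawn fields stay only weakly cross-correlated (mean |r|
below 0.3). Nodata is carved out in spatially contiguous blobs (30% of cells
by default), shared across layers the way oceans are shared across real
global products. Localities sit at centers of valid cells and draw

```
ho = clip(intercept + Σ βᵥ xᵥ + island_effect·1[island] + N(0, noise_sd), 0, 1)
```

Clipping, rather than a logistic transform, keeps the inverse reasoning in
recovery tests simple: inside (0, 1) the generative model is exactly linear.
The defaults mirror the scale of the compiled rat data — 83 localities per
species (the larger per-species complete-case sample), ~30% island records,
intercept 0.5 (between the species means of about 0.45 and 0.62), residual
sd 0.05 Ho units, and a β vector (0.02, 0.08, 0.04, 0.01, −0.04) dominated
by population density, the predictor the compiled data single out.

What the generator does **not** emulate: spatial clustering of sampling
effort (real localities concentrate in cities of studied regions; synthetic
ones are uniform over valid cells), heterogeneous per-study measurement
error, marker-type effects on Ho, non-linear predictor–Ho relationships,
and spatial autocorrelation of residuals. Passing tests therefore
demonstrate that the machinery is correct and that effects of the assumed
form are recovered at realistic sample sizes and noise — not that the
biological conclusions from any real compilation are right.

## Problem sizes in the test suite

The suite favours many small deterministic checks plus a few simulation
checks at deliberately modest sizes: MESS oracle instances up to 50
reference and 100 query points across 100 seeds; dominant-predictor
recovery at n = 200 over 20 seeds (500-tree forests); the jackknife noise
floor at n = 100 over 10 seeds (300-tree refits); end-to-end determinism on
a 24 × 48 grid with 40 localities per species. These sizes give stable
pass/fail behaviour at interactive runtimes while exercising every code
path, and the acceptance script runs the full default scenario (60 × 120
grid, 83 localities per species, the full 10–10,000 tree grid).

## Known limitations

* Raster I/O is plain-text ESRI ASCII grid, one band per file with square
  cells; projected CRS inputs must be converted to geographic coordinates
  upstream.
* The jackknife refits the forest n times; for n in the hundreds this is
  minutes, and for thousands of records k-fold validation would be the
  better tool.
* The MESS mask's median-of-positives rule is conservative by construction;
  users comparing against conventional extrapolation masks should run both
  rules.
* Inference is associative. The Pearson screen, the forest importances and
  the projections say nothing about causation, and no spatial dependence is
  modelled.
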