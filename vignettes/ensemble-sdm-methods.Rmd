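---
title: "Methods: ensemble habitat-suitability modelling in sdmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat-suitability modelling in sdmflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

sdmflow implements a presence-only ensemble species distribution modelling
(SDM) workflow for risk mapping: given occurrence records and gridded
environmental predictors, it estimates where a species could establish, how
confident that estimate is, and how the suitable range shifts under altered
climate scenarios. This vignette is the package's account of the methods:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices, and what the simulation-based validation does and
does not demonstrate.

## The modelling problem and its assumptions

Occurrence data for invasive species are presence-only: we observe where a
species was recorded, never where it is absent. The workflow therefore
contrasts presences against *pseudo-absences* — background locations chosen
to be environmentally unlike the presences — and treats the resulting
binary classification probabilities as a habitat-suitability index in
[0, 1]. The core assumptions are:

* occurrence records, after cleaning and thinning, sample the environmental
  conditions the species tolerates (not necessarily its full range);
* environmental layers at the analysis resolution capture the niche axes
  that matter;
* locations environmentally dissimilar to all presences are acceptable
  stand-ins for absences;
* correlative suitability transfers to moderately shifted climates
  (no dispersal, demography or biotic interactions are modelled).

## Occurrence hygiene

`clean_occurrences()` collapses exact coordinate duplicates and drops
non-finite, out-of-range and out-of-grid coordinates, reporting counts for
each removal class. `rarefy_to_grid()` keeps one record per grid cell (the
first in input order — a deterministic, order-faithful rule).
`spatial_thin()` then enforces a minimum inter-record distance with a
randomized greedy algorithm: repeatedly delete a record with the most
neighbours inside the radius (ties broken at random), run `n_tries`
randomized passes, and keep the pass retaining the most records. Maximum
independent set is NP-hard; this randomized greedy heuristic is the
standard practical compromise and is deterministic under a fixed seed. The
default radius is 5 km — one cell at the 5-km working resolution — because
thinning below the grid resolution would be a no-op after rarefaction, and
larger radii discard data without a documented bias to correct.
Distances are haversine (km) on geographic grids and Euclidean in map units
otherwise; synthetic grids declare equal-area units so 1 map unit = 1 km.

## Pseudo-absence design

`build_sre_envelope()` bounds, for each continuous predictor, the central
`1 - 2q` mass of presence values (empirical quantiles with the
linear-interpolation definition, so hand-computed oracles are unambiguous).
The default `q = 0.025` follows the common surface-range-envelope
convention of trimming 2.5% per tail, which keeps single outlier records
from inflating the envelope.

`sample_pseudo_absences()` resolves the two constraints of the design —
*accessibility* and *environmental dissimilarity* — explicitly: the
background is every data cell within `buffer_km` (default 110 km, a
dispersal-scale radius) of a presence; eligible cells are background cells
that are not presences and fall **outside** the envelope in at least one
variable; each replicate draws `n` cells (default 1,000) uniformly without
replacement, with replicate seeds derived as master + replicate index.
A shortfall of eligible cells is an error, never silently fewer points.
Replicated PA sets (default 10) propagate the arbitrariness of the
background sample into the model battery rather than hiding it.

## Predictor screening

Collinear predictors destabilize regression-family learners and blur
importance attribution. `vifcor_select()` runs the iterative
correlation/VIF loop: find the predictor pair with the largest |Pearson r|;
if it exceeds `r_threshold` (default 0.7), drop the member with the larger
variance inflation factor (`VIF = 1/(1 - R²)` from regressing that
predictor on all others) and repeat. A second explicit phase then drops
max-VIF predictors until all VIF are below `vif_threshold` (default 10).
Ties on VIF drop the later column in input order (logged). Tables larger
than `sample_limit` (default 5,000 rows) are screened on a seeded uniform
subsample. Categorical predictors bypass the screen and are passed through:
Pearson correlation on category codes is meaningless. Every drop is
recorded with the offending pair, its |r| and both VIFs, and the final
report asserts its own invariants (max |r| ≤ threshold, max VIF <
threshold).

## The model battery

Six learners sit behind one contract — map a predictor row to a probability
in [0, 1], deterministically given a seed:

| id | model | key defaults |
|----|-------|--------------|
| GLM | logistic regression, optional quadratic terms | quadratic on |
| GBM | stochastic gradient-boosted trees | depth 3, η 0.1, row subsample 0.5 |
| RF | random forest of classification trees | 300 trees, √p mtry |
| CTA | single classification tree, cost-complexity pruned at min CV error | cp 0.001 |
| MAXNET | elastic net on linear + quadratic + hinge basis | lasso, 4 hinge knots/tail, λ by CV |
| XGBOOST | second-order boosting with shrinkage + column subsampling | depth 4, η 0.1, colsample 0.8 |

GBM and XGBOOST are configured to preserve their distinct inductive
characters: GBM relies on row subsampling with no column subsampling or L2
penalty; XGBOOST on column subsampling and regularization. The MAXNET
basis (linear, scaled quadratic, forward and reverse hinges at interior
quantile knots) is the standard maxent-as-GLM formulation; the elastic-net
penalty is chosen by seeded cross-validation. Categorical predictors are
one-hot expanded for the linear-family learners and consumed as factors by
the tree learners. Presences and pseudo-absences are weighted to equal
total mass (prevalence 0.5) by default, so `n` presences are never swamped
by a larger background sample; this is configurable off.

`tune_hyperparameters()` offers small per-algorithm grids (≤ 8 points)
scored by stratified cross-validated TSS, ties resolving to the earlier
grid point. Tuning is off by default in the pipeline: the battery's
replication over runs × PA sets already absorbs much of the hyperparameter
sensitivity, and the defaults are conventional mid-range settings.

### Evaluation

Data are split 70:30 (training:evaluation) per run, stratified by label so
both classes appear in every partition — without stratification a small
evaluation set can lack a class and leave TSS/AUC undefined. The total
training size is exactly `round(0.7·N)`. Each single model is scored on
its held-out 30% with:

* **AUC**, computed as the Mann–Whitney statistic via midranks (ties count
  half), exact under heavy ties and invariant to monotone transforms;
* **TSS** = sensitivity + specificity − 1, at the threshold maximizing it.
  The candidate set {0, 1, midpoints of consecutive sorted unique
  predictions} provably contains a maximizer of the piecewise-constant TSS
  curve; ties resolve to the smallest threshold.

## The weighted-mean ensemble

Single models with held-out TSS ≥ `tss_min` (default 0.7) become ensemble
members. The ensemble prediction at site *i* is the TSS-weighted mean

$$\mathrm{WA}_i = \frac{\sum_j \mathrm{TSS}_j \, p_{ij}}{\sum_j \mathrm{TSS}_j},$$

a convex combination of member predictions. Weighting by skill rather than
simple averaging lets better models dominate while retaining algorithmic
diversity; filtering first keeps unskilled models from diluting the mean.
The ensemble itself is evaluated with the same AUC/max-TSS machinery on the
pooled held-out rows of all (run × PA) partitions — the union of the
evaluation datasets — and its max-TSS threshold is the binarization cutoff
used downstream (always recorded on the output map).

**Permutation importance** shuffles one predictor column at a time and
scores `1 − r` between original and shuffled-input predictions: 0 means no
influence. For the ensemble, the same permutation is applied to every
member, member scores are combined with the ensemble weights into a
per-shuffle score, and mean ± SD are taken over shuffles (default 3). This
per-member-then-weight aggregation keeps the score exactly 0 for a
predictor no member uses. Note `1 − r` can exceed 1 if shuffling
anti-correlates predictions.

**Uncertainty** is mapped as the per-cell coefficient of variation
(sample SD / mean) of the *continuous* member probabilities. CV on
probabilities, rather than on binarized maps, preserves information about
where members disagree in degree; cells with zero mean are set to nodata
(counted and warned) since CV is undefined there. A single-member ensemble
has no defined CV and the pipeline skips the map.

**Range change** compares two binary maps on one grid:
expansion = suitable only in the future, contraction = suitable only
currently, unchanged = suitable in both, each × cell area. The identities
`unchanged + contraction = current area` and
`unchanged + expansion = future area` hold by construction and are asserted
in tests. Cell area is a scalar on equal-area grids; for geographic grids
`geographic_cell_areas()` supplies cosine-latitude-corrected per-row areas.

## Rasters and grids

Grids are 0-based, row-major, top-left-origin, with half-open cells — fixed
project-wide so cell arithmetic has one convention. Stacks unify their
nodata masks (union over layers): a cell is fully observed or fully
missing. Raster I/O uses ESRI ASCII grids (plain text, printed at 17
significant digits so doubles round-trip bit-exactly) with a JSON sidecar
for layer kinds and period tags. Resampling aggregates blocks by mean
(continuous) or majority with smallest-label tie-break (categorical);
partial blocks use the observed cells and all-nodata blocks stay nodata;
non-divisible dimensions are padded with nodata. The aggregation statistic
is a package choice — block mean/majority is the least surprising default
for climatological and class-dominance layers respectively.

## The virtual-species generator

`simulate_env_stack()` builds continuous layers as moving-average-smoothed
Gaussian noise fields. The fields are column-orthogonalized and mixed
through the Cholesky factor of the target correlation matrix, so empirical
cross-correlations equal the target *exactly* rather than approximately —
tests of collinearity handling then probe the screening logic, not the
generator's sampling noise. A categorical "crop dominance" analog is made
by quantile-binning an additional independent smooth field into equal-area
classes. True suitability is `plogis(β₀ + Σ β_k f_k(x_k))` with linear,
Gaussian, hinge or per-category responses; the logistic link is simple,
differentiable and standard in virtual-species work. Occurrences are drawn
without replacement with probability proportional to suitability (optionally
× a bias field emulating uneven sampling effort). Future scenarios apply
per-layer offsets/factors/noise and categorical relabelling.

What the generator does *not* emulate: mechanistic dispersal limits,
biotic interactions, temporal occurrence error, non-stationary niches, and
the particular covariance structure of real bioclimatic variables. Passing
tests therefore demonstrate that the pipeline recovers niches *of the
assumed logistic form under known sampling*, not that any real species is
modelled correctly.

### The packaged benchmark

`virtual_species_benchmark()` fixes the package's canonical validation
scenario, chosen once as a realistic desk-scale analog of a crop-pest
analysis: a 100 × 100 equal-area grid (1-km cells), six continuous layers
at cross-correlation 0.3 with smoothness 4, one 4-class categorical layer,
and a species driven mainly by one favourable crop class (level effects
−6/−6/−2/+6 around intercept −2) with a secondary Gaussian response
(β = 3, width 2) to one temperature-range analog; 300 presences; a "warm"
scenario shifting that driver +2 SD. The attached configuration uses a
reduced battery (3 PA replicates × 2 CV runs × 4 algorithms, 300
pseudo-absences, 40-km buffer, 1.5-km thinning) so a full end-to-end run
takes seconds; the structural 3 × 10 × 6 = 180-model design point is
exercised on a 50 × 50 variant. These problem sizes are the package's
validation choices: large enough that ensemble skill, importance ranking
and scenario responses are stable across seeds, small enough to run a
ten-seed replication in minutes.

## Numerical and degenerate-input choices

* Seeds: one master seed; child seeds derived by offset (replicates, runs)
  or stage name (pipeline stages), all below 2³¹. Same seed, same result —
  asserted down to manifest content hashes.
* Zero-variance columns correlate as 0 (warned); perfectly collinear
  predictors report VIF = ∞; a constant prediction vector yields
  importance 0 with a warning rather than an undefined correlation.
* Quantiles use the linear-interpolation (type 7) definition everywhere.
* Single-class training or evaluation data raise errors
  (degenerate-training, undefined-metric) rather than returning NaN.
* Factor levels seen at training are frozen into the model; projection onto
  stacks with unseen category labels is a schema error, not a silent
  coercion.
* The ensemble requires ≥ 1 member; an empty selection is an error that
  reports the best achieved TSS so the threshold can be reviewed.

## Known limitations

* ASCII-grid raster I/O is plain-text and single-resolution; there is no
  reprojection — stacks must arrive co-registered.
* Pseudo-absence eligibility asks only that a cell exit the envelope in one
  variable; with many predictors most of the background qualifies, so the
  contrast class is diffuse (by design, but it bounds achievable TSS).
* Permutation importance inherits the usual caveat of correlated
  predictors: importance leaks between correlated layers, and interactions
  are not attributed.
* The ensemble's evaluation pools held-out rows across PA replicates; rows
  can recur across replicates, which slightly understates the variance of
  the pooled estimate.
* Projections assume the fitted response transfers to shifted covariate
  ranges; hinge and tree learners extrapolate flat, GLM quadratics do not.
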