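---
title: "Mapping the 3Cs of vaccine hesitancy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the 3Cs of vaccine hesitancy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

National surveys measure attitudes toward vaccination — trust in vaccine
safety, perceived disease risk, access barriers — but are representative
only at the national or first administrative level. Program planners need
those quantities at the neighbourhood scale. `hesitmap` implements a full
pipeline that takes a georeferenced categorical household survey and an
aligned stack of spatial covariates and produces 1 km^2 raster estimates of
the WHO 3Cs determinants of vaccine hesitancy:

* **Confidence** — trust in vaccine safety and efficacy;
* **Complacency** — low perceived risk from the disease;
* **Convenience** — access, time and financial barriers, built as a
  composite of an *accessibility* and a *time-and-financial-burden*
  sub-index.

The pipeline stages are: survey reweighting (IPF), index construction
(MCA), friction-based accessibility, two-stage cross-validated spatial
interpolation, survey-based layer validation, and zonal analytics
(heterogeneity ranges, mean cumulative scores, prevalent determinant,
population counts, multi-criteria targeting).

## Index construction by MCA

Each determinant is summarized by the first dimension of a correspondence
analysis of the indicator (complete disjunctive) matrix of its categorical
inputs, with survey weights as row masses. Let $Z$ be the $n \times J$
indicator matrix over $Q$ inputs, $r$ the row masses, $c$ the column
masses. The analysis decomposes the standardized residual matrix
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ with $P = D_r Z / Q$. We store the
dimension-1 *standard* column coordinates $B_1 = D_c^{-1/2} v_1$; a
respondent's raw score is the mean of the coordinates of their $Q$ response
categories, which by the CA transition formula equals the row principal
coordinate. This makes scoring new respondents a pure lookup, with unseen
categories an explicit error rather than silent imputation.

Design choices that were genuinely open:

* **Indicator-matrix (not Burt) MCA**, because the individual respondent is
  the unit of analysis and row coordinates are the index.
* **Sign**: dimension-1 orientation from SVD is arbitrary, so every index
  spec names an *anchor input* and a direction (e.g. agreement with
  "vaccines may not be safe" must *lower* the confidence index); the fitted
  model flips the coordinates if needed.
* **Explained variance** is reported both raw and Benzecri-corrected
  ($\lambda^\* = ((Q/(Q-1))(\lambda - 1/Q))^2$ for $\lambda > 1/Q$). The
  corrected share is used for the "at least 90%" diagnostic because the raw
  indicator-matrix share cannot approach 90% with several multi-category
  inputs; the diagnostic threshold defaults to 0.74, the weakest primary
  dimension observed in the motivating application (its accessibility
  index; all its attitudinal indices exceeded 0.90 — our synthetic run
  reproduces exactly this pattern, ~0.77 for accessibility and >0.99
  elsewhere).
* **Missing responses** drop the respondent from that index's fit (listwise
  per index); indicator-matrix MCA has no canonical missing category here.
* **Normalization** to 0–100 uses the weighted-sample min/max stored in the
  model, so re-scoring is reproducible; out-of-range scores on new data are
  clipped with a warning.
* **Terciles** are weighted thirds of the 0–100 score, closed on the left
  (a score strictly greater than a cutpoint enters the upper class);
  coincident cutpoints collapse to two levels with a warning.
* **Composite convenience** sums the two *normalized* sub-indices and
  re-normalizes; whether the source analysis summed before or after
  normalization is not stated, and summing after makes the composite
  invariant to the sub-indices' raw scales.
* Continuous inputs (travel times) enter after weighted-quantile binning
  (default 3 bins, ties to the lower bin) since the method operates on
  categorical data only.

## Survey reweighting

`ipf_rake()` is classical raking: multiplicative updates over the margin
list in order, until every weighted category share matches its reference
target within `tol` (default 1e-6, max 100 cycles). Weights are normalized
to sum to the survey n so the 0–100 index normalization is weight-scale
free. Structural zeros (a category with positive target but no
respondents) are an error naming the category; non-convergence is a
reported state, never silent. No trimming by default; a cap is available.
The margins shipped as defaults (urbanicity 53/47, gender 49/51, asset
ownership 45/55) play the role of the urbanicity/gender/asset scaling
factors of a national reference frame.

## Accessibility and travel time

Travel time to the nearest medium-or-large health facility is a
multi-source least-cost distance over a friction raster (minutes/metre):
8-connectivity, step cost equal to the mean of the two cells' friction
times the step length (`cell_size`, diagonal times $\sqrt 2$), computed by
exact Dijkstra on the lattice graph. The facility-size filter is an input
(`filter_facilities()`), not a constant. Homogeneity (scaling friction by
$c$ scales times by $c$) and monotonicity under added facilities are
asserted properties.

## Spatial interpolation

Cluster-level weighted means of each target (index scores rescaled to
[0,1], or tercile shares) are regressed on covariates sampled at cluster
centroids. The stages:

1. **Covariate selection**: covariates ranked by absolute weighted
   correlation with the target, forward-selected on grouped k-fold CV RMSE
   with a 1-SE stop (OLS as the selection learner).
2. **Learner pool** (configurable registry): elastic net (`glmnet`, with an
   explicit lambda path extended to ~0 so noiseless linear signals can be
   fitted unpenalized), a thin-plate spatial GAM (`mgcv`), k-nearest
   neighbours on coordinates (`FNN`), and OLS. The environment provides no
   random-forest or boosting backend, so the pool substitutes GAM and OLS
   for them; the registry accepts any learner with `fit`/`predict`.
3. **Candidates**: every learner is cross-validated on *both* the selected
   subset and the full covariate set, with one fold assignment per target
   derived from the seed; folds are whole clusters by construction (one
   frame row per cluster). Because the full set — the *null model* — is
   always among the candidates, the final model can never lose to it:
   `null_model_check()` then re-derives the null RMSE identically and
   reports the comparison. Equal covariate sets are evaluated in a
   canonical column order so the equality is exact, not approximate.
4. **Ensembling**: all candidates within one CV standard error of the best
   are averaged (at most one entry per learner), matching the plural
   "final model(s)".
5. **Two stages**: demographic/socioeconomic targets are interpolated
   first from the base covariates; their predicted layers join the stack
   (as `s1_*`) before attitudinal targets are fitted, letting opinion
   layers borrow strength from associated demographic surfaces. An empty
   stage-1 list reduces exactly to the single-stage pipeline.

Predictions are clipped to declared bounds ([0,1] for shares and scaled
scores) with a clip count, and nodata propagates. Tercile share layers are
renormalized cellwise to sum to one (all-zero cells get equal thirds and a
flag).

In the orchestrated pipeline the standardized log travel-time layers are
appended to the covariate stack before interpolation — they are "derived
data products" in the same sense as the imagery covariates, and the
accessibility component of convenience is not otherwise visible to the
learners.

## Validation

The survey is representative at state level, so each predicted layer is
checked there: the population-weighted raster mean per state is compared
with the weighted survey mean, and the absolute difference is judged
against a 95% cluster-bootstrap CI of the survey mean (clusters resampled
within zone, 500 replicates by default, seeded). A zone passes when the
raster mean falls inside the CI; failing zones are carried forward as
caution flags — a failing validation yields a completed run with status
"caution", never a crash. Population weighting of raster means is the
default (an unweighted option exists); the CI method is our choice, as the
source describes the check but not its interval construction.

## Zonal analytics

Aggregation to any zone raster gives population-weighted means, cell
min/max and population totals. Heterogeneity is summarized by range widths
(max − min) at national/state/LGA/hyperlocal levels — aggregation can only
shrink ranges, an invariant asserted on every synthetic run — and by the
**Mean Cumulative Score**: the sum of the three per-index widths divided by
three, rounded to the nearest integer half away from zero (the only
rounding consistent with all four published worked examples: 91/3 → 30,
166/3 → 55, 31/3 → 10, 113/3 → 38). The **prevalent determinant** is the
cellwise argmax of {100 − confidence, complacency, 100 − convenience};
ties break by a configurable priority (default convenience > complacency >
confidence). People counts multiply tercile share layers by the population
raster; multi-criteria targeting filters a zone-stats table by arbitrary
(column, comparator, threshold) triples, with "majority" read as strictly
greater than 50% (configurable — the source's footnoted thresholds are not
available).

## The synthetic world

Real inputs of this kind (a 2022 national phone survey and a commercial
covariate stack) are not public, so the package ships a generator whose
defaults state the world once:

* 60 × 60 grid of 1 km cells; 6 states × 4 LGAs (rectangular partitions —
  no real geography);
* 120 clusters × 41 respondents = 4,920 (the source survey had 4,922);
* 12 covariates as a desk-scale stand-in for "approximately 130": Gaussian
  random fields built as white noise convolved with a separable Gaussian
  kernel (correlation length 6 cells), standardized;
* latent construct surfaces linear in the covariates (a fixed loading
  matrix in which every construct loads on urbanicity plus two specific
  covariates) plus smooth spatial noise (sd 0.4 on the logit scale);
* categorical items drawn from logistic (binary) or cumulative-logistic
  (3-level) models of the *cell-level* latent, with intercepts placed so
  national prevalences sit in the 20–80% band and discriminations
  1.0–1.6;
* friction surfaces around 12 min/km walking and 1 min/km driving,
  cheaper where latent accessibility is high; ~30 facilities placed with
  probability increasing in urbanicity; population ~250 persons/cell,
  log-linear in urbanicity;
* cluster coordinates are cell centres (no DHS-style displacement);
  coordinates are metres from the grid origin, with CRS as pass-through
  metadata.

The truth surfaces for confidence/complacency are min-max rescalings of the
latents; the accessibility truth blends the measured log travel times with
the latent (70/30) so ground truth and measurable signal agree, and the
convenience truth is the rescaled sum of the accessibility and
time-financial latents.

What a green test does and does not establish: the generator produces
smooth, covariate-driven fields with honest sampling noise, so it exercises
recovery, validation and analytics end to end; it does not emulate phone
survey nonresponse, quota fielding, within-cluster heterogeneity of the
kind cities produce, or real Nigerian geography, and no result on it says
anything about real Nigerian attitudes. Interpolation recovery on the
default seed-1 world reaches r ≈ 0.89–0.95 against truth; across other
seeds it typically spans ~0.65–0.97 with CV RMSEs of 0.03–0.09 on the unit
scale, so the published "RMSE below 0.05" is a diagnostic to report, not a
guarantee of this desk-scale world.

## Numerical conventions

Rasters are row-major, north-up, half-open cells $[x, x+\Delta)$ so edge
points resolve deterministically; on-disk rasters are plain-text ESRI ASCII
grids written at 17 significant digits (lossless for doubles) because the
environment provides no GeoTIFF-capable R package. Weighted quantiles use
the sort-and-accumulate lower convention with a 1e-12 boundary tolerance.
All stochastic steps (world generation, folds, bootstrap) run under
explicit seeds; identical configs give byte-identical reports. IPF
converges on the synthetic margins in ~6 cycles (the source reports 3 on
its data; the count is data-dependent and not hard-coded).

## Known limitations

Appendix-level details of the original ensemble (exact learners, selection
mechanics) are unavailable; every default here is a declared decision. No
uncertainty rasters are produced. Kriging-style geostatistics and road
network routing are out of scope. The CLI covers `simulate` and `run`; the
individual stages are exposed as R functions rather than subcommands.
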