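---
title: "Modelling farm biosecurity and antimicrobial usage: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling farm biosecurity and antimicrobial usage: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amuplan)
```

## The modelling problem

Cross-sectional surveys of broiler farms record, per farm, a few dozen
mostly binary biosecurity answers (hygiene locks, stable-specific clothing,
water-system cleaning, depopulation practice, ...), three size/productivity
covariates, and total antimicrobial usage as TIDDDvet — treatment days per
1000 animal-days, so TIDDDvet/10 is the percent of a broiler's life under
treatment. Farms cluster within countries, usage is right-skewed with exact
zeros and a heavy tail, and the interesting signal is not the net effect of
any single measure but how measures combine on a particular farm. `amuplan`
fits one predictive model to such data and then interrogates it, farm by
farm, for the intervention combinations predicted to reduce usage, with
costs attached.

## Outcome and covariate transforms

Usage is modelled as `z = log(ti + 1)`. The shift keeps zero-usage farms
finite while compressing the tail; it is strictly increasing, so farm
orderings survive the transform. The inverse `exp(z) - 1` reports
predictions back in TIDDDvet units; model predictions below the transform
of zero (rare, but possible for a forest averaged with a negative country
intercept) are clamped to zero with a warning rather than reported as
negative usage. The transform lives in one function (`transform_amu()`) so
an alternative started-log or shifted-root choice is a one-line swap.

Broilers per round and worker counts are natural-log transformed (scale and
outliers); rounds per year enters untouched. Measures missing in more than
10% of farms, or whose minority answer among non-missing farms falls below
15%, are excluded — a nearly unanimous answer cannot support a split, and
heavy missingness makes the indicator level dominate the measure. The 15%
rule is applied to the share of the minority level *among non-missing
answers*; remaining missingness becomes an explicit third factor level
("missing indicator"), not an imputed value, so the model can learn from
missingness itself at the prediction stage.

## The mixed-effects random forest

Countries shift usage levels for reasons the survey does not measure
(regulation, market structure, climate), so the model is
`z_i = f(x_i) + b_g(i) + e_i` with a regression forest `f`, a country
random intercept `b_g ~ N(0, sigma_b^2)` and residual `e_i ~ N(0,
sigma_e^2)`. Fitting alternates:

1. fit the forest to `y - b` (current intercepts removed);
2. update each intercept as the shrunken mean of its country's
   **out-of-bag** residuals, `b_g = n_g sigma_b^2 / (n_g sigma_b^2 +
   sigma_e^2) * mean(r_g)` — the BLUP under the current variances;
3. update the variance components from the posterior moments.

Out-of-bag rather than in-bag residuals matter here: a forest's in-sample
residuals are shrunk almost to zero, which would starve the intercepts.
The loop stops when the largest intercept change drops below `em_tol`
(default 1e-4), after `max_em_iter` iterations (default 50), or — in
practice the binding rule — when the update stops shrinking for two
consecutive iterations. The last rule exists because the intercept update
contracts quickly to the forest's out-of-bag resampling jitter (about
0.05–0.1 on typical data) and then fluctuates without converging further;
waiting for 1e-4 would simply burn the full iteration budget for no change
in the fit. The trace of penalised residual sums is kept on the model
object for inspection.

Defaults follow regression-forest practice: 500 trees, `mtry = floor(p/3)`
(7 for a 21-predictor model). With a single country `sigma_b^2` is
unidentifiable and forced to zero, and the fit provably reduces to an
ordinary forest (a unit test asserts prediction equality). A constant
outcome triggers a zero-variance warning. One seed controls bootstrap
resampling and split tie-breaks, so fits are exactly reproducible.

Proximities — the fraction of trees in which two farms share a terminal
node — are computed over **all** observations and all trees (the classical
definition), not out-of-bag pairs only; entries are therefore exact
multiples of 1/n_trees, symmetric, with a unit diagonal.

## Recursive feature elimination

Variable selection runs a country-stratified k-fold cross-validation
(default 10 folds; stratification keeps every country in every training
split, otherwise the intercepts of a left-out country would be
inestimable). Within each training split the model is refitted repeatedly,
dropping the single least Gini-important predictor each time — no batch
dropping, ties broken by column order — until `floor(0.25 * p0)` remain
(13 from 53). Predictors are then pooled by the number of folds that kept
them; for each threshold t the subset "kept by at least t folds" is
re-evaluated by cross-validated RMSE on the transformed scale, and the
lowest mean RMSE wins, ties going to the larger t (sparser model).
Thresholds with empty subsets are skipped.

Two properties are guaranteed by construction and tested: threshold
subsets are nested, and the selected threshold attains the minimum CV RMSE
among the evaluated thresholds. We deliberately do *not* claim the
selected subset always beats a model using every column: forests are
robust to noise columns, and a very sparse subset with `mtry = floor(p/3)`
can lose more predictive richness than the noise columns cost. The value
of the elimination is interpretability and stability of the downstream
effect estimates, not raw RMSE.

## Clustering and prototypes

Farm dissimilarity `1 - P` from the final model's proximity matrix is
embedded by classical metric MDS in 3 dimensions (the dimensionality used
for visual inspection; degenerate spectra are zero-padded). k-means with
25 restarts runs for k = 2..10, and k is selected by the BIC of the
spherical equal-variance Gaussian formulation of the k-means objective.
Farms are labelled High/Low users by min-max normalising the observed and
predicted transformed usage and cutting at 0.5 — a deliberately simple,
affine-invariant rule; a constant vector degenerates to all-Low with a
warning. Per (cluster × predicted class) cell, prototypes are the median
for numeric fields and the modal level (with its frequency) for binary
fields; empty cells (e.g. a cluster with only Low users) are marked not
applicable, and modal ties break toward "measure applied" and are flagged.

Clustering runs on the 3-D embedding rather than the raw n × n
dissimilarity: the embedding is what the analyst inspects, and spherical
BIC is only meaningful in a Euclidean space of fixed dimension.

## Effect sizes, consistency and the expectation filter

The effect of a binary measure is its partial dependence difference: mean
prediction with the measure forced to 1 on every farm minus the mean with
it forced to 0, all other columns untouched. This equals the brute-force
two-counterfactual average by definition, and a test enforces exact
agreement against an independent naive implementation. Country intercepts
cancel in the difference. Before effects are computed, remaining "missing"
levels are resolved to 0/1 by chained-equation imputation with
classification-forest conditional models (mode initialisation, five
sweeps, deterministic under seed) — an authored, minimal MICE-style loop.

Uncertainty comes from a nonparametric farm-level bootstrap, resampling
with replacement *within* country (keeping every country present so the
intercepts stay estimable), refitting, and recomputing the effect; the
percentile interval at 95% is reported, 1000 replicates by default
(tests and examples use fewer).

Forest effect sizes of weak predictors can flip sign between refits. The
pipeline is therefore refitted ten times on the same data with consecutive
seeds — the variability being addressed is the randomness intrinsic to the
ensemble, not sampling variability, so the data are not resampled — and
only measures whose effect sign agrees in all ten runs may enter plans.

A farm's measures are then classified by the cross-table of current answer
× effect sign: applied & negative, or not applied & positive, is a
strength; the other two cells are weaknesses, the candidate action points.
Finally, weaknesses survive only if the estimated direction matches the
measure's expected biological direction (an editable YAML:
protective/risky/unclear). A measure that is biologically protective but
estimated risky looks like reverse causality — farms adopting it *because*
they have a usage problem — and stays in the model as a predictor but
never becomes a recommendation. "Unclear" measures are never recommended.

## Scenario planning and costs

All `2^k - 1` nonempty combinations of a farm's candidate weaknesses are
evaluated (capped at k = 15); each scenario flips its measures on the
farm's row, every consistency-run model predicts, predictions are
back-transformed to TIDDDvet and averaged across runs, and scenarios below
the identically-averaged baseline are kept. Back-transforming *before*
averaging keeps the report in interpretable TIDDDvet units and matches how
a mean of per-run usages would be read; the averaging order is a design
choice, not a mathematical necessity. Kept scenarios are numbered so the
largest reduction carries the highest number, and the report lists best
first.

Costs per measure are straight-line depreciation (implementation cost over
lifetime) plus yearly operation plus an optional production-scaled term
(per animal × rounds, per round, or per stable, with stable count
defaulting to 2 when unrecorded). Scenario cost is the sum over flipped
measures; cost-effectiveness divides yearly cost by the TIDDDvet change,
so reductions give negative euro-per-unit values. Prices ship as an
editable YAML; the packaged example book is illustrative, not a price
survey — its three intervention items total 8644.87 euro/yr (and 1644.87
excluding one-step depopulation) so that end-to-end cost arithmetic has a
fixed, testable reference.

## The synthetic generator and what the tests show

`generate_farms()` emulates the survey structure the analysis assumes:
9 countries × 20 farms by default, independent binary measures at
configurable prevalences, log-normal broiler counts (median ≈ 35 000),
integer rounds 5–8, small log-normal worker counts, a Gaussian country
intercept, sparse planted main effects and optional pairwise interactions
on the transformed scale, Gaussian noise, back-transformation with
clamping at zero, a configurable fraction of exact-zero farms, and
optional per-cell missingness. Ground truth (planted effects, planted
intercepts, implied expectation table) is exposed for recovery tests.

It deliberately does **not** emulate: the correlation structure of real
biosecurity surveys (measures co-occur on well-run farms), country-specific
prevalences or cost structures, or any association between covariates and
measures. Passing recovery tests therefore demonstrates that the pipeline
finds the structure it is designed to find under its own assumptions — not
that those assumptions hold on any real survey, where confounding and
reverse causality remain the analyst's problem.

Reference conditions used by the recovery benchmarks and the acceptance
script: 180 farms in 9 countries, 30 measures at prevalence 0.5 (maximal
information per measure; planted measures at skewed prevalences would
confound recovery power with prevalence), three planted effects of |0.8|,
country-intercept SD 1.0, residual SD 0.3, no zero inflation. Forests in
these runs use 100 trees and an EM budget of 3 iterations — sizes chosen so
a full 20-replicate elimination study runs on a laptop in minutes while
leaving recovery rates saturated well above the thresholds tested; the
bootstrap-coverage study uses 200 replicates of a 60-farm, 6-measure
survey with 40-replicate bootstraps.

## Numerical choices and degenerate inputs

* Transform round-trips exactly (`log1p`/`expm1`); negative usage input is
  an error, negative *predicted* transformed usage clamps to 0 with a
  warning.
* Importance ties during elimination break by column order; modal ties in
  prototypes break toward level 1 and are flagged; RMSE ties across
  thresholds break toward the sparser subset.
* k-means BIC uses the spherical ML variance `WSS / (d (n - k))` guarded
  at 1e-12; empty-subset thresholds and empty candidate sets produce
  messages, not errors.
* A feature that is entirely missing cannot be imputed and errors; a
  constant feature still yields a (zero-ish) computable effect because
  partial dependence forces both levels.
* All stochastic steps (generation, forest fits, folds, restarts,
  bootstrap, imputation) are seeded; rerunning a pipeline with an
  identical configuration is bit-identical, and every artefact is stamped
  with a configuration hash that ignores file locations.

## Limitations

Cross-sectional associations are not causal effects; the consistency and
expectation filters remove measures *showing evidence of* non-causal
association, which is weaker than establishing causality. The model cannot
predict exact-zero usage (a hurdle-style extension would be needed), so
plans for already-zero farms should be read as risk profiles, not
reduction forecasts. Scenario predictions extrapolate a farm into measure
combinations that may be rare in the training data; the forest then
predicts from the nearest observed profiles, and wide bootstrap intervals
are the warning sign.
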