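# amuplan

Farm-specific antimicrobial-usage reduction plans from broiler biosecurity
data.

## The problem

Broiler farms differ widely in which biosecurity measures they apply and in
how much antimicrobials they use. Usage is recorded as **TIDDDvet** —
treatment incidence based on Defined Daily Doses per 1000 animal-days, so
TIDDDvet/10 is the percentage of a broiler's life spent under treatment
(150 TIDDDvet = 15%). Because measures interact, the *same* intervention can
pay off on one farm and do nothing on another; net per-measure risk factors
are a poor basis for farm-level advice. `amuplan` is for veterinary
epidemiologists and advisors who want quantitative, farm-specific,
cost-annotated recommendations from cross-sectional survey data spanning
several countries.

## The method

The outcome is modelled on a started-log scale, `z = log(TIDDDvet + 1)`
(finite at zero usage, tames a handful of extreme farms), with a
**mixed-effects random forest**:

    z_i = f(x_i) + b_g(i) + e_i,   b_g ~ N(0, sigma_b^2),  e_i ~ N(0, sigma_e^2)

where `f` is a regression forest over the biosecurity measures and three
size/productivity covariates (log broilers per round, rounds per year, log
workers), and `b_g` is a country-level random intercept. Fitting alternates
forest fits on `y - b` with BLUP-style intercept updates from out-of-bag
residuals (EM-style).

Around this model the package implements:

* **RF-RFE** — per-fold recursive elimination by Gini importance down to
  the top 25% of predictors, cross-fold frequency subsets, and final subset
  selection by minimum cross-validated RMSE;
* **proximity clustering** — the fraction of trees in which two farms share
  a terminal node, embedded by classical MDS, k-means with BIC-selected k,
  High/Low-user labelling and per-cluster class prototypes;
* **effect sizes** — partial-dependence effects of each binary measure with
  within-country bootstrap confidence intervals, a 10-refit
  sign-consistency rule, and a biological-expectation filter that excludes
  measures whose association looks reverse-causal;
* **the planner** — each farm's measures are classified as strengths or
  weaknesses (current answer × effect sign); all `2^k - 1` combinations of
  candidate weaknesses are predicted, and scenarios beating the farm's
  baseline prediction are reported with yearly cost (depreciation +
  operation + production-scaled terms) and cost-effectiveness in euro per
  TIDDDvet unit of reduction;
* **a synthetic-data generator** with planted effects, prevalences, country
  intercepts and zero-usage farms, used by all parameter-recovery tests.

## Worked example

```r
library(amuplan)

# simulate a 3-country survey with two planted biosecurity effects
sim <- synthetic_config(
  n_countries = 3, farms_per_country = 20, n_features = 8,
  feature_prevalences = 0.5,
  true_effects = c(q_001 = -0.8, q_002 = 0.8),
  interaction_terms = list(), sigma_country = 0.7, sigma_noise = 0.2,
  zero_inflation = 0, seed = 7)
farms <- generate_farms(sim)

filt <- filter_features(farms)
X <- encode_features(farms, filt$retained)
y <- transform_amu(farms$tiddd)

cfg  <- mixrf_config(n_trees = 200, seed = 7)
cons <- run_consistency(impute_missing_levels(X), y, farms$country,
                        n_runs = 10, mixrf_cfg = cfg)
round(colMeans(cons$effects), 3)
#>  q_001  q_002  q_003  q_004  q_005  q_006  q_007  q_008
#> -0.609  0.541 -0.008  0.012 -0.013 -0.031  0.003 -0.001
cons$sign_consistency
#> q_001 q_002 q_003 q_004 q_005 q_006 q_007 q_008
#>    10    10    10     9    10    10     6     8
```

The planted effects (-0.8 on `q_001`, +0.8 on `q_002`) are recovered with
the right signs and full 10/10 sign consistency; the noise measures hover
near zero and several fail the consistency rule, which is exactly what
keeps them out of intervention plans. Now plan for a farm that has both
planted measures in their harmful state:

```r
eff <- data.frame(feature = colnames(cons$effects),
                  effect = colMeans(cons$effects),
                  consistent = cons$consistent)
farm <- impute_missing_levels(X)[1, , drop = FALSE]
farm$q_001 <- 0; farm$q_002 <- 1
cand <- plan_candidates(farm, eff, expectations_from_truth(sim))
plan <- evaluate_plan(farm, farms$country[1], enumerate_scenarios(cand),
                      cons$models, original_ti = farms$tiddd[1],
                      farm_id = "F001")
costs <- list(q_001 = cost_item("q_001", 4000, 10, 250),
              q_002 = cost_item("q_002", 0, 1, 700))
print(attach_costs(plan, costs, farms[1, , drop = FALSE]))
#> AMU reduction plan for farm F001
#>   observed TIDDDvet: 192.268   baseline prediction: 293.30
#>          id     flipped predicted_ti pct_change kept yearly_cost cost_per_ti
#>  Scenario_3 q_001+q_002        99.46      -66.1 TRUE        1350       -6.96
#>  Scenario_2       q_001       174.47      -40.5 TRUE         650       -5.47
#>  Scenario_1       q_002       186.32      -36.5 TRUE         700       -6.54
```

Reading the best row: implementing measure `q_001` and dropping `q_002`
together is predicted to cut this farm's usage from 293 to 99 TIDDDvet
(-66.1%), at 1350 euro/year, i.e. about 6.96 euro per TIDDDvet unit of
reduction per year (negative sign = cost per unit reduced). For real
surveys, per-measure prices live in an editable YAML cost book
(`inst/extdata/costs_example.yaml`) and expected biological directions in
an expectation YAML (`inst/extdata/expectations_example.yaml`); the
end-to-end driver is `run_pipeline()`.

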