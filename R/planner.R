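#' Enumerate intervention scenarios
#'
#' One scenario per nonempty subset of the candidate interventions
#' (2^k - 1 scenarios for k candidates). The candidate set is capped at 15
#' to guard against combinatorial explosion; pre-filter the candidates
#' (e.g. by effect size) above that.
#'
#' @param candidates character vector of candidate intervention measures.
#' @return List of character vectors, each the measures flipped in one
#'   scenario; empty list (with a message) for an empty candidate set.
#' @export
enumerate_scenarios <- function(candidates) {
  k <- length(candidates)
  if (k == 0L) {
    message("enumerate_scenarios: no candidate interventions; empty plan")
    return(list())
  }
  if (k > 15L) {
    stop("enumerate_scenarios: ", k, " candidates give 2^", k,
         " - 1 scenarios; pre-filter to at most 15")
  }
  unlist(lapply(seq_len(k), function(m)
    utils::combn(candidates, m, simplify = FALSE)), recursive = FALSE)
}

#' Refit the model repeatedly and record effect-sign consistency
#'
#' Forest effect sizes of weak predictors can flip sign between refits
#' purely through the randomness intrinsic to the ensemble. The pipeline is
#' therefore refitted `n_runs` times on the same data with distinct seeds;
#' a measure is sign-consistent only if its partial-dependence effect has
#' the same (nonzero) sign in every run. Only consistent measures should
#' enter scenarios; predictions are later averaged over the same runs.
#'
#' @param X,y,groups training data as in [fit_mixrf()].
#' @param features measures whose effects are tracked (default as in
#'   [estimate_effects()]).
#' @param n_runs number of refits (default 10; must be >= 2).
#' @param mixrf_cfg base [mixrf_config()]; run r uses seed `seed + r - 1`.
#' @return List: `models` (one fitted model per run), `effects` (runs x
#'   features matrix), `sign_consistency` (named count of the majority
#'   sign, 0..n_runs) and `consistent` (named logical, count == n_runs).
#' @export
run_consistency <- function(X, y, groups,
                            features = setdiff(colnames(X),
                                               c("log_broilers_per_round",
                                                 "rounds_per_year",
                                                 "log_n_workers")),
                            n_runs = 10, mixrf_cfg = mixrf_config()) {
  if (n_runs < 2) stop("run_consistency: n_runs must be >= 2")
  models <- vector("list", n_runs)
  eff <- matrix(NA_real_, n_runs, length(features),
                dimnames = list(NULL, features))
  for (r in seq_len(n_runs)) {
    cfg <- mixrf_cfg
    cfg$seed <- mixrf_cfg$seed + r - 1L
    models[[r]] <- fit_mixrf(X, y, groups, cfg)
    for (f in features) eff[r, f] <- partial_effect(models[[r]], X, f)
  }
  consistency <- apply(eff, 2, function(e)
    max(sum(e > 0), sum(e < 0)))
  list(models = models, effects = eff,
       sign_consistency = consistency,
       consistent = consistency == n_runs)
}

#' Percent change of a scenario prediction against baseline
#'
#' `(scenario_ti - baseline_ti) / baseline_ti * 100`; negative values are
#' AMU reductions. Reported to one decimal place in plan tables. A zero
#' baseline leaves the change undefined (`NA` with a warning).
#'
#' @param baseline_ti baseline predicted TIDDDvet.
#' @param scenario_ti scenario predicted TIDDDvet.
#' @return Signed percent change (full precision).
#' @export
percent_change <- function(baseline_ti, scenario_ti) {
  if (any(baseline_ti <= 0)) {
    warning("percent_change: baseline is zero; change undefined")
    return(NA_real_)
  }
  (scenario_ti - baseline_ti) / baseline_ti * 100
}

#' Evaluate scenarios for one farm
#'
#' For each scenario the listed measures are flipped (0 <-> 1) on the farm's
#' predictor row; each of the consistency-run models predicts the
#' transformed AMU (including the farm's country intercept when known), the
#' prediction is back-transformed to TIDDDvet, and the mean over runs is the
#' scenario's predicted usage. The baseline is the unmodified row evaluated
#' the same way. Scenarios predicting below baseline are kept and numbered
#' `Scenario_1` (smallest reduction) to `Scenario_m` (largest); rejected
#' ones are labelled `rejected_*`. Rows are ordered by ascending predicted
#' TIDDDvet, so the best scenario comes first.
#'
#' @param farm_row one-row predictor frame (training columns, measures 0/1).
#' @param farm_group the farm's country label (or `NA` for unknown).
#' @param scenarios list from [enumerate_scenarios()].
#' @param models list of fitted models from [run_consistency()].
#' @param original_ti the farm's observed TIDDDvet (carried into the
#'   report; optional).
#' @param farm_id farm identifier for the report.
#' @return An object of class `plan_report`: `farm_id`, `original_ti`,
#'   `baseline_prediction_ti` and a `scenarios` data.frame with columns
#'   `id`, `flipped`, `predicted_ti`, `pct_change`, `kept`.
#' @export
evaluate_plan <- function(farm_row, farm_group, scenarios, models,
                          original_ti = NA_real_, farm_id = NA_character_) {
  stopifnot(nrow(farm_row) == 1L, length(models) >= 1L)
  predict_mean_ti <- function(row) {
    preds <- vapply(models, function(m)
      predict(m, row, groups = farm_group, include_random = TRUE),
      numeric(1))
    mean(suppressWarnings(inverse_transform_amu(preds)))
  }
  for (m in models) {
    if (!identical(colnames(farm_row), m$feature_names)) {
      stop("evaluate_plan: farm columns do not match the model")
    }
  }
  baseline <- predict_mean_ti(farm_row)

  rows <- lapply(scenarios, function(flip) {
    bad <- setdiff(flip, colnames(farm_row))
    if (length(bad)) stop("evaluate_plan: unknown measure(s): ",
                          paste(bad, collapse = ", "))
    row <- farm_row
    for (f in flip) row[[f]] <- 1 - row[[f]]
    ti <- predict_mean_ti(row)
    data.frame(flipped = paste(flip, collapse = "+"),
               predicted_ti = ti,
               pct_change = percent_change(baseline, ti),
               kept = ti < baseline,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(flipped = character(0), predicted_ti = numeric(0),
               pct_change = numeric(0), kept = logical(0))
  tab <- tab[order(tab$predicted_ti), , drop = FALSE]
  ids <- character(nrow(tab))
  m_kept <- sum(tab$kept)
  ids[tab$kept] <- sprintf("Scenario_%d", rev(seq_len(m_kept)))
  if (any(!tab$kept)) {
    ids[!tab$kept] <- sprintf("rejected_%d", seq_len(sum(!tab$kept)))
  }
  tab <- cbind(id = ids, tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  structure(list(
    farm_id = farm_id,
    original_ti = original_ti,
    baseline_prediction_ti = baseline,
    scenarios = tab
  ), class = "plan_report")
}

#' @export
print.plan_report <- function(x, digits = 2, ...) {
  cat("AMU reduction plan for farm", x$farm_id, "\n")
  cat(sprintf("  observed TIDDDvet: %s   baseline prediction: %.2f\n",
              format(x$original_ti), x$baseline_prediction_ti))
  tab <- x$scenarios
  tab$predicted_ti <- round(tab$predicted_ti, digits)
  tab$pct_change <- round(tab$pct_change, 1)
  if ("yearly_cost" %in% names(tab)) {
    tab$yearly_cost <- round(tab$yearly_cost, 2)
    tab$cost_per_ti <- round(tab$cost_per_ti, 2)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}
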