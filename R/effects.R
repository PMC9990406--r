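#' Impute missing-indicator levels by chained equations
#'
#' Effect sizes and scenario predictions need every biosecurity measure as a
#' plain 0/1 value, so the "missing" category introduced by
#' [encode_features()] is resolved by multivariate imputation by chained
#' equations with classification-forest conditional models: missing cells
#' start at the observed mode, then each incomplete measure is repeatedly
#' re-imputed from all other predictors until the sweep count is exhausted.
#' Deterministic under the seed.
#'
#' @param X encoded predictor frame; measures with missing answers are
#'   three-level factors (`"0"/"1"/"missing"`).
#' @param sweeps chained-equation sweeps (default 5).
#' @param n_trees trees per conditional forest (default 100).
#' @param seed integer seed.
#' @return `X` with every measure as numeric 0/1.
#' @export
impute_missing_levels <- function(X, sweeps = 5, n_trees = 100, seed = 1L) {
  Xn <- X
  incomplete <- character(0)
  for (f in names(Xn)) {
    if (is.factor(Xn[[f]])) {
      v <- as.character(Xn[[f]])
      v[v == "missing"] <- NA
      Xn[[f]] <- as.numeric(v)
      if (anyNA(Xn[[f]])) incomplete <- c(incomplete, f)
      if (all(is.na(Xn[[f]]))) {
        stop("impute_missing_levels: feature ", f, " is entirely missing")
      }
    }
  }
  if (!length(incomplete)) return(Xn)

  miss_idx <- lapply(Xn[incomplete], function(v) which(is.na(v)))
  for (f in incomplete) {   # initialise at the observed mode
    obs <- Xn[[f]][!is.na(Xn[[f]])]
    mode_val <- as.numeric(names(which.max(table(obs))))
    Xn[[f]][miss_idx[[f]]] <- mode_val
  }
  for (s in seq_len(sweeps)) {
    for (f in incomplete) {
      idx <- miss_idx[[f]]
      obs <- setdiff(seq_len(nrow(Xn)), idx)
      fit <- ranger::ranger(
        x = Xn[obs, setdiff(names(Xn), f), drop = FALSE],
        y = factor(Xn[[f]][obs], levels = c(0, 1)),
        num.trees = n_trees, num.threads = 1,
        seed = seed + s, classification = TRUE)
      pred <- stats::predict(fit,
                             data = Xn[idx, setdiff(names(Xn), f),
                                       drop = FALSE],
                             num.threads = 1)$predictions
      Xn[[f]][idx] <- as.numeric(as.character(pred))
    }
  }
  Xn
}

#' Partial-dependence effect size of a binary measure
#'
#' The effect on transformed AMU of a one-unit change in the measure while
#' averaging over all other variables: the mean forest prediction with the
#' measure forced to 1 on every farm minus the mean prediction with it
#' forced to 0 (all other columns untouched). Country intercepts cancel in
#' the difference. A negative effect means applying the measure predicts
#' lower AMU.
#'
#' @param model fitted [fit_mixrf()] model (trained on imputed, all-numeric
#'   measures).
#' @param X predictor frame with the training columns.
#' @param feature name of a 0/1 measure column.
#' @return Signed scalar effect on the transformed AMU scale.
#' @export
partial_effect <- function(model, X, feature) {
  if (!feature %in% colnames(X)) {
    stop("partial_effect: unknown feature ", feature)
  }
  if (!is.numeric(X[[feature]])) {
    stop("partial_effect: feature must be numeric 0/1 (impute first)")
  }
  X1 <- X; X1[[feature]] <- 1
  X0 <- X; X0[[feature]] <- 0
  mean(predict(model, X1, groups = NULL, include_random = FALSE)) -
    mean(predict(model, X0, groups = NULL, include_random = FALSE))
}

#' Effect sizes for a set of measures
#'
#' @param model fitted [fit_mixrf()] model.
#' @param X predictor frame.
#' @param features measures to evaluate (default: all numeric 0/1 columns
#'   apart from the covariates).
#' @return `data.frame` with `feature` and `effect`.
#' @export
estimate_effects <- function(model, X,
                             features = setdiff(colnames(X),
                                                c("log_broilers_per_round",
                                                  "rounds_per_year",
                                                  "log_n_workers"))) {
  data.frame(
    feature = features,
    effect = vapply(features, function(f) partial_effect(model, X, f),
                    numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bootstrap confidence interval for an effect size
#'
#' Nonparametric farm-level bootstrap: farms are resampled with replacement
#' within their country (so every replicate keeps all countries and the
#' random intercepts stay estimable), the mixed-effects forest is refitted,
#' and the partial-dependence effect recomputed. The percentile interval of
#' the bootstrap distribution at the requested level is returned.
#'
#' @param X,y,groups training data as in [fit_mixrf()].
#' @param feature measure whose effect is bootstrapped.
#' @param n_boot bootstrap replicates (default 1000).
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @param mixrf_cfg [mixrf_config()] for the refits.
#' @return List with `ci_low`, `ci_high`, `effect` (full-data point
#'   estimate) and `boot_effects` (the replicate values).
#' @export
bootstrap_ci <- function(X, y, groups, feature, n_boot = 1000, level = 0.95,
                         seed = 1L, mixrf_cfg = mixrf_config()) {
  if (n_boot < 10) stop("bootstrap_ci: n_boot must be >= 10")
  stopifnot(level > 0, level < 1)
  groups <- as.character(groups)
  full <- fit_mixrf(X, y, groups, mixrf_cfg)
  point <- partial_effect(full, X, feature)

  by_country <- split(seq_along(groups), groups)
  eff <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_country, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    cfg_b <- mixrf_cfg
    cfg_b$seed <- mixrf_cfg$seed + b
    fit_b <- fit_mixrf(X[idx, , drop = FALSE], y[idx], groups[idx], cfg_b)
    eff[b] <- partial_effect(fit_b, X[idx, , drop = FALSE], feature)
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(eff, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], effect = point, boot_effects = eff)
}

#' Classify measures as a farm's strengths or weaknesses
#'
#' Cross-table of the farm's current answer against the effect-size sign: a
#' measure is a strength if the farm already applies it and applying it
#' predicts lower AMU (value 1, negative effect), or does not apply it and
#' applying it predicts higher AMU (value 0, positive effect). The opposite
#' combinations are weaknesses -- the candidate action points. Measures with
#' an exactly zero effect are skipped with a warning.
#'
#' @param farm_values named 0/1 vector: the farm's current answers.
#' @param effects named signed effect sizes (transformed-AMU scale).
#' @return `data.frame` with `feature`, `farm_value`, `effect`,
#'   `effect_sign` and `label` ("strength"/"weakness").
#' @export
classify_measures <- function(farm_values, effects) {
  feats <- intersect(names(farm_values), names(effects))
  rows <- list()
  for (f in feats) {
    e <- effects[[f]]
    v <- farm_values[[f]]
    if (!v %in% c(0, 1)) stop("classify_measures: farm value for ", f,
                              " must be 0/1 (impute first)")
    if (e == 0) {
      warning("classify_measures: effect for ", f, " is exactly 0; skipped")
      next
    }
    label <- if ((v == 1 && e < 0) || (v == 0 && e > 0)) "strength"
             else "weakness"
    rows[[f]] <- data.frame(feature = f, farm_value = v, effect = e,
                            effect_sign = ifelse(e > 0, "+", "-"),
                            label = label, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(feature = character(0), farm_value = numeric(0),
                      effect = numeric(0), effect_sign = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only weaknesses whose association is biologically plausible
#'
#' A measure's estimated association may contradict its biological
#' interpretation (e.g. reverse causality in a cross-sectional design:
#' farms adopt a measure *because* they have a usage problem). Such measures
#' remain useful predictors but are not proposed as interventions. A
#' weakness is kept only when the estimated effect sign matches the expected
#' direction: "protective" measures must show a negative effect of applying
#' them, "risky" ones a positive effect. Expectations marked "unclear", and
#' measures absent from the table, are dropped (the latter with a warning).
#'
#' @param classified output of [classify_measures()].
#' @param expectations named character vector or list mapping feature to
#'   `"protective"`, `"risky"` or `"unclear"` (see [read_expectations()]).
#' @return The weakness rows retained as candidate interventions.
#' @export
filter_by_expectation <- function(classified, expectations) {
  expectations <- unlist(expectations)
  weak <- classified[classified$label == "weakness", , drop = FALSE]
  keep <- logical(nrow(weak))
  for (i in seq_len(nrow(weak))) {
    f <- weak$feature[i]
    if (!f %in% names(expectations)) {
      warning("filter_by_expectation: no biological expectation for ", f,
              "; dropped")
      next
    }
    exp_dir <- expectations[[f]]
    keep[i] <- (exp_dir == "protective" && weak$effect[i] < 0) ||
               (exp_dir == "risky" && weak$effect[i] > 0)
  }
  out <- weak[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a biological-expectation table
#'
#' YAML file mapping each measure to its expected direction of association
#' with AMU: `protective` (applying it should reduce usage), `risky`
#' (applying it should increase usage) or `unclear`. The file is
#' user-editable; an example covering the common biosecurity measures ships
#' in `inst/extdata/expectations_example.yaml`.
#'
#' @param path YAML file path.
#' @return Named character vector of expected directions.
#' @export
read_expectations <- function(path) {
  x <- unlist(yaml::read_yaml(path))
  bad <- setdiff(unique(x), c("protective", "risky", "unclear"))
  if (length(bad)) {
    stop("read_expectations: invalid direction(s): ",
         paste(bad, collapse = ", "))
  }
  x
}
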