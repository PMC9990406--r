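#' Transform total AMU to the modelling scale
#'
#' Treatment incidence (TIDDDvet, treatment days per 1000 animal-days) is
#' right-skewed with occasional extreme farms and exact zeros, so modelling
#' is done on a started-log scale: `z = log(ti + 1)`. The shift keeps zero
#' usage finite (a plain log would map it to -Inf) while compressing the
#' heavy right tail. The transform is strictly increasing, so orderings of
#' farms are preserved.
#'
#' @param ti non-negative TIDDDvet value(s).
#' @return Transformed value(s), `log(ti + 1)`.
#' @seealso [inverse_transform_amu()]
#' @export
transform_amu <- function(ti) {
  if (any(!is.finite(ti)) || any(ti < 0)) {
    stop("transform_amu: TIDDDvet values must be finite and >= 0")
  }
  log1p(ti)
}

#' Back-transform a modelled value to the TIDDDvet scale
#'
#' Exact inverse of [transform_amu()]: `ti = exp(z) - 1`. Model predictions
#' can occasionally fall below the transform of zero; those are clamped to 0
#' with a warning, since negative usage is meaningless.
#'
#' @param z value(s) on the transformed scale.
#' @return Non-negative TIDDDvet value(s).
#' @export
inverse_transform_amu <- function(z) {
  if (any(z < 0)) {
    warning("predictions below the transform of zero clamped to 0 TIDDDvet")
    z <- pmax(z, 0)
  }
  expm1(z)
}

#' TIDDDvet as percentage of life under treatment
#'
#' A TIDDDvet of `ti` treatment days per 1000 animal-days means broilers are
#' treated during `ti / 10` percent of their life (e.g. 150 TIDDDvet = 15%).
#'
#' @param ti TIDDDvet value(s).
#' @return Percentage(s) of life under antimicrobial treatment.
#' @export
tiddd_to_pct_life <- function(ti) ti / 10

#' Exclude uninformative biosecurity measures
#'
#' Drops measures with more than `missing_max` missing answers or with less
#' than `variation_min` variation. Variation of a binary measure is the share
#' of its minority level among non-missing answers; a measure almost every
#' farm answers the same way carries no usable signal.
#'
#' Missingness is assessed first: a measure failing both rules is reported
#' under `excluded_missing` only, so the report lists are disjoint.
#'
#' @param farms farm table (see [generate_farms()] for the shape).
#' @param missing_max maximum tolerated missing fraction (default 0.10).
#' @param variation_min minimum minority-level share among non-missing
#'   answers (default 0.15).
#' @return A list with `retained` (feature names kept) and `report`, a
#'   `preprocess_report` with `excluded_missing`, `excluded_lowvar` and
#'   `indicator_features` (retained measures that still carry missing cells
#'   and will receive a missing-indicator level in [encode_features()]).
#' @export
filter_features <- function(farms, missing_max = 0.10, variation_min = 0.15) {
  if (is.null(nrow(farms)) || nrow(farms) == 0L) {
    stop("filter_features: farm table is empty")
  }
  feats <- feature_cols(farms)
  excluded_missing <- character(0)
  excluded_lowvar <- character(0)
  indicator <- character(0)
  retained <- character(0)
  for (f in feats) {
    v <- farms[[f]]
    miss_frac <- mean(is.na(v))
    if (miss_frac > missing_max) {
      excluded_missing <- c(excluded_missing, f)
      next
    }
    obs <- v[!is.na(v)]
    minority <- if (length(obs)) min(mean(obs == 1), mean(obs == 0)) else 0
    if (minority < variation_min) {
      excluded_lowvar <- c(excluded_lowvar, f)
      next
    }
    retained <- c(retained, f)
    if (miss_frac > 0) indicator <- c(indicator, f)
  }
  report <- structure(list(
    excluded_missing = excluded_missing,
    excluded_lowvar = excluded_lowvar,
    indicator_features = indicator
  ), class = "preprocess_report")
  list(retained = retained, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocess report\n")
  cat("  excluded (>10% missing):  ", length(x$excluded_missing), "\n")
  cat("  excluded (<15% variation):", length(x$excluded_lowvar), "\n")
  cat("  missing-indicator level:  ", length(x$indicator_features), "\n")
  invisible(x)
}

#' Build the model matrix
#'
#' Encodes a farm table into the predictor frame the forest is fitted on:
#' broilers per round and number of workers are natural-log transformed
#' (outliers and rescaling), rounds per year enters untouched, and each
#' retained binary measure is kept as 0/1. A measure with remaining missing
#' answers becomes a three-level factor `"0"/"1"/"missing"` (the missing
#' indicator method): missingness is treated as its own answer category
#' rather than imputed at this stage.
#'
#' @param farms farm table.
#' @param retained feature names to encode (from [filter_features()]).
#' @return `data.frame` with columns `log_broilers_per_round`,
#'   `rounds_per_year`, `log_n_workers` and the encoded measures.
#' @export
encode_features <- function(farms, retained = feature_cols(farms)) {
  if (any(farms$broilers_per_round <= 0) || any(farms$n_workers <= 0)) {
    stop("encode_features: broilers_per_round and n_workers must be positive for log transform")
  }
  out <- data.frame(
    log_broilers_per_round = log(farms$broilers_per_round),
    rounds_per_year = farms$rounds_per_year,
    log_n_workers = log(farms$n_workers)
  )
  for (f in retained) {
    v <- farms[[f]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("encode_features: feature ", f, " has values outside {0, 1, missing}")
    }
    if (anyNA(v)) {
      lv <- as.character(v)
      lv[is.na(lv)] <- "missing"
      out[[f]] <- factor(lv, levels = c("0", "1", "missing"))
    } else {
      out[[f]] <- as.numeric(v)
    }
  }
  stopifnot(!anyNA(out[c("log_broilers_per_round", "rounds_per_year",
                         "log_n_workers")]))
  out
}
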