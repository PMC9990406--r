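#' RFE configuration
#'
#' Settings for cross-validated recursive feature elimination
#' ([run_rfe()]): `k_folds` cross-validation folds (stratified by country so
#' every training split contains every country, keeping the random
#' intercepts estimable) and the fraction of the starting predictors each
#' fold retains after elimination.
#'
#' @param k_folds number of CV folds (default 10).
#' @param keep_fraction fraction of starting predictors each fold keeps
#'   (default 0.25; for 53 predictors this is the top 13).
#' @param seed integer seed for the fold assignment.
#' @param mixrf mixrf configuration used for the per-fold fits; defaults to
#'   [mixrf_config()].
#' @return An object of class `rfe_config`.
#' @export
rfe_config <- function(k_folds = 10, keep_fraction = 0.25, seed = 1L,
                       mixrf = mixrf_config()) {
  stopifnot(k_folds >= 2, keep_fraction > 0, keep_fraction < 1,
            inherits(mixrf, "mixrf_config"))
  structure(list(k_folds = as.integer(k_folds),
                 keep_fraction = as.numeric(keep_fraction),
                 seed = as.integer(seed), mixrf = mixrf),
            class = "rfe_config")
}

#' Root mean square error
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L) stop("rmse: empty vectors")
  if (length(y) != length(yhat)) stop("rmse: length mismatch")
  sqrt(mean((y - yhat)^2))
}

# Number of predictors kept after elimination: floor of the keep fraction
# applied to the starting count (53 -> 13 at 25%).
rfe_keep_target <- function(p0, keep_fraction) {
  as.integer(floor(keep_fraction * p0))
}

#' Importance-driven elimination within one training split
#'
#' Fits the mixed-effects forest on all current predictors, removes the
#' single predictor with the lowest Gini importance, refits, and repeats
#' until only the top `keep_fraction` of the starting predictors remain
#' (`floor(keep_fraction * p0)`; ties on importance are broken by column
#' order).
#'
#' @param X_train training predictor frame.
#' @param y_train training outcome (transformed scale).
#' @param groups_train training country labels.
#' @param keep_fraction fraction of starting predictors to keep.
#' @param mixrf_cfg [mixrf_config()] for the repeated fits.
#' @return Character vector of retained predictor names.
#' @export
eliminate_within_fold <- function(X_train, y_train, groups_train,
                                  keep_fraction = 0.25,
                                  mixrf_cfg = mixrf_config()) {
  p0 <- ncol(X_train)
  if (p0 < 2L) stop("eliminate_within_fold: need at least 2 predictors")
  target <- rfe_keep_target(p0, keep_fraction)
  if (target < 1L) {
    stop("eliminate_within_fold: keep target below 1 (", p0, " predictors, ",
         "keep_fraction ", keep_fraction, ")")
  }
  current <- colnames(X_train)
  while (length(current) > target) {
    fit <- fit_mixrf(X_train[, current, drop = FALSE], y_train, groups_train,
                     mixrf_cfg)
    imp <- gini_importance(fit)
    drop_feat <- names(imp)[which.min(imp)]
    current <- setdiff(current, drop_feat)
  }
  current
}

#' Cross-validated recursive feature elimination
#'
#' Selects the predictor subset that best predicts transformed AMU:
#' \enumerate{
#'   \item Split farms into `k_folds` country-stratified folds.
#'   \item Within each training split, eliminate predictors one at a time by
#'     Gini importance down to the top `keep_fraction`
#'     ([eliminate_within_fold()]).
#'   \item Count, for each predictor, in how many folds it survived.
#'   \item For each frequency threshold t = 1..k, form the subset of
#'     predictors appearing in at least t folds, refit on every training
#'     split with that subset and average the test-fold RMSE.
#'   \item Pick the threshold with the lowest mean RMSE; ties go to the
#'     larger threshold (the sparser model). Thresholds with an empty
#'     subset are skipped.
#' }
#'
#' @param X predictor frame (from [encode_features()]).
#' @param y outcome on the transformed scale.
#' @param groups country labels.
#' @param config an [rfe_config()].
#' @return An object of class `rfe_result`: per-fold subsets, predictor
#'   frequencies, per-threshold subsets and mean RMSEs, the selected
#'   threshold and `final_features`.
#' @export
run_rfe <- function(X, y, groups, config = rfe_config()) {
  stopifnot(inherits(config, "rfe_config"))
  n <- nrow(X)
  stopifnot(length(y) == n, length(groups) == n)
  folds <- make_folds(groups, config$k_folds, config$seed)

  fold_subsets <- vector("list", config$k_folds)
  for (k in seq_len(config$k_folds)) {
    tr <- folds != k
    fold_subsets[[k]] <- eliminate_within_fold(
      X[tr, , drop = FALSE], y[tr], groups[tr],
      keep_fraction = config$keep_fraction, mixrf_cfg = config$mixrf)
  }

  freq <- table(factor(unlist(fold_subsets), levels = colnames(X)))
  freq <- stats::setNames(as.integer(freq), colnames(X))

  thresholds <- seq_len(config$k_folds)
  threshold_subsets <- lapply(thresholds, function(t)
    names(freq)[freq >= t])
  names(threshold_subsets) <- thresholds
  mean_rmse <- rep(NA_real_, config$k_folds)
  names(mean_rmse) <- thresholds
  for (t in thresholds) {
    sub <- threshold_subsets[[t]]
    if (length(sub) == 0L) next
    errs <- numeric(config$k_folds)
    for (k in seq_len(config$k_folds)) {
      tr <- folds != k
      fit <- fit_mixrf(X[tr, sub, drop = FALSE], y[tr], groups[tr],
                       config$mixrf)
      pred <- predict(fit, X[!tr, sub, drop = FALSE], groups[!tr],
                      include_random = TRUE)
      errs[k] <- rmse(y[!tr], pred)
    }
    mean_rmse[t] <- mean(errs)
  }
  ok <- which(!is.na(mean_rmse))
  if (!length(ok)) stop("run_rfe: no threshold produced a nonempty subset")
  best <- max(ok[mean_rmse[ok] == min(mean_rmse[ok])])  # tie -> sparser

  structure(list(
    folds = folds,
    fold_subsets = fold_subsets,
    feature_frequencies = freq,
    threshold_subsets = threshold_subsets,
    mean_rmse = mean_rmse,
    selected_threshold = best,
    final_features = threshold_subsets[[best]]
  ), class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("RF-RFE result\n")
  cat(sprintf("  selected threshold: appears in >= %d of %d folds\n",
              x$selected_threshold, length(x$fold_subsets)))
  cat(sprintf("  mean RMSE at selection: %.4f\n",
              x$mean_rmse[x$selected_threshold]))
  cat("  final predictors:", paste(x$final_features, collapse = ", "), "\n")
  invisible(x)
}

# Country-stratified fold assignment: farms are shuffled within country and
# dealt round-robin so every fold (and hence every training split) covers
# every country.
make_folds <- function(groups, k, seed) {
  n <- length(groups)
  folds <- integer(n)
  set.seed(seed)
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    folds[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  folds
}

#' Flag predictors above the uniform-importance threshold
#'
#' A heuristic for which predictors to describe as most important: with N
#' predictors, those contributing more than 1/N of the total Gini importance
#' exceed what a fully uninformative split of importance would give them
#' (for N = 21 the threshold is 1/21 = 4.76%).
#'
#' @param importances normalised importances (summing to 1).
#' @return Logical vector: `TRUE` where the share strictly exceeds 1/N.
#' @export
importance_contribution_flags <- function(importances) {
  n <- length(importances)
  if (!n) return(logical(0))
  importances > 1 / n
}
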