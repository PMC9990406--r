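#' Mixed-effects random forest configuration
#'
#' Tuning parameters for [fit_mixrf()]. Defaults follow common forest
#' practice for regression: 500 trees and `mtry = floor(p / 3)` candidate
#' predictors per split (for a 21-predictor model this gives 7). The EM-style
#' fitting loop alternates forest fits with random-intercept updates; it is
#' capped at `max_em_iter` iterations and declared converged when the
#' largest intercept change drops below `em_tol`.
#'
#' @param n_trees number of trees (default 500).
#' @param mtry candidate predictors per split; `NULL` means `floor(p / 3)`
#'   (at least 1), resolved at fit time.
#' @param max_em_iter maximum EM iterations (default 50).
#' @param em_tol convergence tolerance on the intercept update (default 1e-4).
#' @param seed integer seed controlling bootstrap resampling and split
#'   tie-breaking, for reproducibility.
#' @return An object of class `mixrf_config`.
#' @export
mixrf_config <- function(n_trees = 500, mtry = NULL, max_em_iter = 50,
                         em_tol = 1e-4, seed = 1L) {
  stopifnot(n_trees >= 1, max_em_iter >= 1, em_tol > 0)
  if (!is.null(mtry)) stopifnot(mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 max_em_iter = as.integer(max_em_iter),
                 em_tol = as.numeric(em_tol), seed = as.integer(seed)),
            class = "mixrf_config")
}

#' Default mtry rule
#'
#' Regression-forest default: one third of the predictors, rounded down,
#' never below one. For 21 predictors this yields 7.
#'
#' @param p number of predictors.
#' @return Integer mtry.
#' @export
default_mtry <- function(p) max(1L, as.integer(floor(p / 3)))

#' Fit a mixed-effects random forest
#'
#' Farms are clustered within countries, so outcome levels shift between
#' countries for reasons (climate, regulation, market) not captured by the
#' measured predictors. The model is
#' \deqn{y_i = f(x_i) + b_{g(i)} + \varepsilon_i,\quad b_g \sim N(0, \sigma_b^2),\ \varepsilon_i \sim N(0, \sigma_e^2)}
#' with \eqn{f} a regression forest. Fitting alternates, EM-style:
#' (a) fit the forest to \eqn{y - b}; (b) form out-of-bag residuals
#' \eqn{r_i = y_i - \hat f_{oob}(x_i)} and update each intercept as the
#' shrunken group mean \eqn{b_g = n_g \sigma_b^2 / (n_g \sigma_b^2 + \sigma_e^2) \bar r_g}
#' (the BLUP under known variances); (c) update the variance components from
#' the posterior moments. Out-of-bag (rather than in-bag) residuals are used
#' so the forest's in-sample overfit does not swallow the group structure.
#'
#' With a single country the intercept variance is unidentifiable and is
#' forced to zero, reducing the fit to an ordinary regression forest. A
#' constant outcome yields a zero-variance warning.
#'
#' @param X predictor `data.frame` (from [encode_features()]).
#' @param y outcome on the transformed AMU scale.
#' @param groups country labels, one per row of `X`.
#' @param config a [mixrf_config()].
#' @return An object of class `mixrf`: the forest, per-country intercepts,
#'   variance components `sigma2_b` / `sigma2_e`, the training column order
#'   and the EM trace (penalised residual sum of squares per iteration).
#' @export
fit_mixrf <- function(X, y, groups, config = mixrf_config()) {
  stopifnot(inherits(config, "mixrf_config"))
  n <- nrow(X)
  if (length(y) != n || length(groups) != n) {
    stop("fit_mixrf: X, y and groups must have matching lengths")
  }
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  if (stats::var(y) == 0) {
    warning("fit_mixrf: outcome is constant (zero variance)")
  }
  mtry <- if (is.null(config$mtry)) default_mtry(ncol(X)) else
    min(config$mtry, ncol(X))

  single_group <- length(glev) < 2L
  gmeans <- tapply(y, groups, mean)
  sigma2_b <- if (single_group) 0 else max(stats::var(as.numeric(gmeans)), 1e-8)
  sigma2_e <- max(stats::var(y), 1e-8)
  b <- stats::setNames(numeric(length(glev)), glev)
  ng <- as.numeric(table(groups)[glev])

  trace <- numeric(0)
  fit <- NULL
  best_delta <- Inf
  stall <- 0L
  for (iter in seq_len(config$max_em_iter)) {
    ystar <- y - b[groups]
    fit <- ranger::ranger(x = X, y = ystar, num.trees = config$n_trees,
                          mtry = mtry, importance = "impurity",
                          num.threads = 1, seed = config$seed,
                          oob.error = TRUE)
    f_oob <- fit$predictions               # oob estimate of f(x)
    if (anyNA(f_oob)) {                    # rows never out-of-bag (few trees)
      pin <- stats::predict(fit, data = X, num.threads = 1)$predictions
      f_oob[is.na(f_oob)] <- pin[is.na(f_oob)]
    }
    r <- y - f_oob
    if (single_group || sigma2_b == 0) {
      b_new <- b * 0
      vg <- rep(0, length(glev))
    } else {
      rbar <- tapply(r, factor(groups, levels = glev), mean)
      shrink <- ng * sigma2_b / (ng * sigma2_b + sigma2_e)
      b_new <- stats::setNames(shrink * as.numeric(rbar), glev)
      vg <- sigma2_b * sigma2_e / (ng * sigma2_b + sigma2_e)
    }
    eps <- r - b_new[groups]
    trace <- c(trace, sum(eps^2))
    delta <- max(abs(b_new - b))
    b <- b_new
    if (!single_group) {
      sigma2_b <- mean(b^2 + vg)
      sigma2_e <- (sum(eps^2) + sum(ng * vg)) / n
    } else {
      sigma2_e <- mean(eps^2)
    }
    if (delta < config$em_tol) break
    # the intercept update contracts down to the forest's out-of-bag
    # resampling jitter and then fluctuates; stop once it no longer shrinks
    if (delta >= 0.9 * best_delta) {
      stall <- stall + 1L
      if (stall >= 2L && iter >= 3L) break
    } else {
      stall <- 0L
    }
    best_delta <- min(best_delta, delta)
  }

  structure(list(
    forest = fit,
    random_intercepts = b,
    sigma2_b = sigma2_b,
    sigma2_e = sigma2_e,
    feature_names = colnames(X),
    mtry = mtry,
    config = config,
    em_trace = trace,
    n_iter = length(trace)
  ), class = "mixrf")
}

#' @export
print.mixrf <- function(x, ...) {
  cat("Mixed-effects random forest\n")
  cat(sprintf("  trees: %d, mtry: %d, predictors: %d\n",
              x$config$n_trees, x$mtry, length(x$feature_names)))
  cat(sprintf("  sigma2_b: %.4f  sigma2_e: %.4f  (EM iterations: %d)\n",
              x$sigma2_b, x$sigma2_e, x$n_iter))
  cat("  countries:", paste(names(x$random_intercepts), collapse = " "), "\n")
  invisible(x)
}

#' Predict transformed AMU for farms
#'
#' Forest prediction plus, when `include_random` is on and the farm's
#' country was seen in training, that country's intercept. Farms from
#' unknown countries get the population-level prediction (intercept 0).
#'
#' @param object fitted [fit_mixrf()] model.
#' @param X predictor frame with exactly the training columns.
#' @param groups country labels, or `NULL` for population-level predictions.
#' @param include_random add the country intercept (default `TRUE`).
#' @param ... unused.
#' @return Numeric vector on the transformed AMU scale.
#' @export
predict.mixrf <- function(object, X, groups = NULL, include_random = TRUE,
                          ...) {
  if (!identical(colnames(X), object$feature_names)) {
    stop("predict.mixrf: columns of X do not match the training columns")
  }
  p <- stats::predict(object$forest, data = X,
                      num.threads = 1)$predictions
  if (include_random && !is.null(groups)) {
    groups <- as.character(groups)
    known <- groups %in% names(object$random_intercepts)
    add <- numeric(length(groups))
    add[known] <- object$random_intercepts[groups[known]]
    p <- p + add
  }
  p
}

#' Gini importance of the fitted forest
#'
#' Per-predictor total impurity (response variance) reduction summed over
#' all split nodes and trees, normalised to sum to one. A predictor never
#' selected for a split has importance zero.
#'
#' @param model fitted [fit_mixrf()] model.
#' @return Named non-negative numeric vector summing to 1 (all zeros if the
#'   forest contains no informative split).
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "mixrf"))
  imp <- model$forest$variable.importance
  imp <- pmax(imp, 0)
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

#' Random-forest proximity matrix
#'
#' Pairwise similarity of farms under the fitted forest: the fraction of
#' trees in which two farms fall in the same terminal node, over all trees
#' and all observations. Entries lie in \[0, 1\] with a unit diagonal; 1 - P
#' is the dissimilarity used for multidimensional scaling.
#'
#' @param model fitted [fit_mixrf()] model.
#' @param X predictor frame (training columns).
#' @return An n x n symmetric matrix of class `proximity_matrix`.
#' @export
rf_proximity <- function(model, X) {
  stopifnot(inherits(model, "mixrf"))
  if (!identical(colnames(X), model$feature_names)) {
    stop("rf_proximity: columns of X do not match the training columns")
  }
  nodes <- stats::predict(model$forest, data = X, type = "terminalNodes",
                          num.threads = 1)$predictions
  n <- nrow(nodes)
  ntree <- ncol(nodes)
  P <- matrix(0, n, n)
  for (t in seq_len(ntree)) {
    P <- P + outer(nodes[, t], nodes[, t], "==")
  }
  P <- P / ntree
  structure(P, class = c("proximity_matrix", "matrix"))
}
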