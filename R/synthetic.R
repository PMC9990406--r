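#' Configuration for the synthetic farm-data generator
#'
#' Defines the statistical structure of a simulated cross-sectional broiler
#' survey: a set of countries each contributing a fixed number of farms, a
#' panel of binary biosecurity measures with configurable prevalences, three
#' farm-size/productivity covariates, and a total antimicrobial usage (AMU)
#' outcome on the TIDDDvet scale (treatment days per 1000 animal-days).
#'
#' The outcome is built on the transformed scale as
#' \deqn{z = \beta_0 + X\beta + \sum_{(i,j)} \gamma_{ij} x_i x_j + c(\mathrm{covariates}) + b_{country} + \varepsilon}
#' with \eqn{b \sim N(0, \sigma_b^2)} and \eqn{\varepsilon \sim N(0, \sigma_e^2)},
#' then back-transformed to TIDDDvet with [inverse_transform_amu()] (values
#' below the transform of zero clamp to zero). A configurable fraction of
#' farms is overwritten with exactly zero usage, mimicking farms that used no
#' antimicrobials in the observation period.
#'
#' Defaults emulate a nine-country survey with twenty farms per country and
#' 53 mostly binary biosecurity measures. Planted main effects are sparse:
#' most features are pure noise and a handful carry signed effects on the
#' transformed-AMU scale, so that recovery of the planted structure can be
#' tested. Covariate effects default to negative (larger, more intensive
#' farms using less antimicrobials per animal-day).
#'
#' @param n_countries number of countries (default 9).
#' @param farms_per_country farms sampled per country (default 20). May be a
#'   vector of length `n_countries` for unbalanced designs.
#' @param n_features number of binary biosecurity measures (default 53),
#'   named `q_001` ... `q_NNN`.
#' @param feature_prevalences per-feature probability of level 1. A single
#'   value is recycled; default spreads prevalences evenly over 0.2--0.8.
#' @param true_effects named numeric vector of planted main effects on the
#'   transformed-AMU scale; names must be feature names. Unnamed features
#'   have effect 0. Default plants five effects (-0.8, -0.5, +0.6, -0.4,
#'   +0.8) on the first five measures.
#' @param interaction_terms list of `list(feature_i, feature_j, effect)`
#'   triples; default one synergistic pair.
#' @param covariate_effects length-3 numeric: effects of log(broilers per
#'   round), rounds per year and log(workers) on the transformed scale.
#' @param intercept baseline transformed AMU for an average farm (default
#'   3.5, about 32 TIDDDvet).
#' @param sigma_country SD of the country-level random intercept (default 1).
#' @param sigma_noise residual SD on the transformed scale (default 0.5).
#' @param zero_inflation probability that a farm's TIDDDvet is overwritten
#'   with exactly 0 (default 0.03).
#' @param missing_features character vector of features subject to
#'   missingness (default none).
#' @param missing_rate per-cell missingness probability for
#'   `missing_features` (default 0.05).
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed and the configuration.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_farms()], [ground_truth()]
#' @export
synthetic_config <- function(n_countries = 9,
                             farms_per_country = 20,
                             n_features = 53,
                             feature_prevalences = NULL,
                             true_effects = NULL,
                             interaction_terms = NULL,
                             covariate_effects = c(-0.30, -0.15, -0.20),
                             intercept = 3.5,
                             sigma_country = 1.0,
                             sigma_noise = 0.5,
                             zero_inflation = 0.03,
                             missing_features = character(0),
                             missing_rate = 0.05,
                             seed = 1L) {
  feature_names <- sprintf("q_%03d", seq_len(n_features))
  if (is.null(feature_prevalences)) {
    feature_prevalences <- seq(0.2, 0.8, length.out = n_features)
  }
  if (length(feature_prevalences) == 1L) {
    feature_prevalences <- rep(feature_prevalences, n_features)
  }
  if (is.null(true_effects)) {
    k <- min(5L, n_features)
    true_effects <- c(-0.8, -0.5, 0.6, -0.4, 0.8)[seq_len(k)]
    names(true_effects) <- feature_names[seq_len(k)]
  }
  if (is.null(interaction_terms) && n_features >= 7) {
    interaction_terms <- list(list(feature_names[6], feature_names[7], 0.4))
  }
  if (is.null(interaction_terms)) interaction_terms <- list()
  if (length(farms_per_country) == 1L) {
    farms_per_country <- rep(farms_per_country, n_countries)
  }

  cfg <- structure(list(
    n_countries = as.integer(n_countries),
    farms_per_country = as.integer(farms_per_country),
    n_features = as.integer(n_features),
    feature_names = feature_names,
    feature_prevalences = as.numeric(feature_prevalences),
    true_effects = true_effects,
    interaction_terms = interaction_terms,
    covariate_effects = as.numeric(covariate_effects),
    intercept = as.numeric(intercept),
    sigma_country = as.numeric(sigma_country),
    sigma_noise = as.numeric(sigma_noise),
    zero_inflation = as.numeric(zero_inflation),
    missing_features = as.character(missing_features),
    missing_rate = as.numeric(missing_rate),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_countries < 1L) stop("n_countries must be >= 1")
  if (length(cfg$farms_per_country) != cfg$n_countries) {
    stop("farms_per_country must have length 1 or n_countries")
  }
  if (any(cfg$farms_per_country < 1L)) stop("farms_per_country must be >= 1")
  if (cfg$n_features < 1L) stop("n_features must be >= 1")
  if (length(cfg$feature_prevalences) != cfg$n_features) {
    stop("feature_prevalences must have length 1 or n_features")
  }
  if (any(cfg$feature_prevalences < 0 | cfg$feature_prevalences > 1)) {
    stop("feature_prevalences must lie in [0, 1]")
  }
  if (length(cfg$true_effects) && is.null(names(cfg$true_effects))) {
    stop("true_effects must be a named vector (names = feature names)")
  }
  bad <- setdiff(names(cfg$true_effects), cfg$feature_names)
  if (length(bad)) stop("true_effects names not among features: ",
                        paste(bad, collapse = ", "))
  for (it in cfg$interaction_terms) {
    if (length(it) != 3L) stop("each interaction term must be (feature_i, feature_j, effect)")
    if (!all(c(it[[1]], it[[2]]) %in% cfg$feature_names)) {
      stop("interaction term references unknown feature")
    }
  }
  if (length(cfg$covariate_effects) != 3L) {
    stop("covariate_effects must have length 3")
  }
  if (cfg$sigma_country < 0 || cfg$sigma_noise < 0) stop("SDs must be >= 0")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1) {
    stop("zero_inflation must lie in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]")
  }
  bad <- setdiff(cfg$missing_features, cfg$feature_names)
  if (length(bad)) stop("missing_features not among features: ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Generate a synthetic farm table
#'
#' Simulates one cross-sectional farm survey from a [synthetic_config()].
#' Binary measures are drawn independently per farm at their configured
#' prevalences; covariates are drawn as broilers per round (log-normal around
#' a median of about 35 000 birds), integer rounds per year in 5--8, and a
#' small log-normal worker count. The transformed outcome is the linear
#' predictor (planted fixed effects, interactions, country intercept) plus
#' Gaussian noise, back-transformed to the TIDDDvet scale; zero-inflated
#' farms are overwritten with 0 and designated cells set missing.
#'
#' Covariate contributions are centred at typical values (log broilers at
#' log(35000), rounds at 6.5, log workers at log(2)) so that `intercept`
#' remains the transformed AMU of an average farm.
#'
#' @param config a [synthetic_config()].
#' @return A `data.frame` with columns `farm_id`, `country`,
#'   `broilers_per_round`, `rounds_per_year`, `n_workers`, `tiddd` and one
#'   0/1 (or `NA`) column per biosecurity measure.
#' @export
generate_farms <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  n <- sum(cfg$farms_per_country)
  set.seed(cfg$seed)

  country <- rep(sprintf("C%02d", seq_len(cfg$n_countries)),
                 times = cfg$farms_per_country)
  b_country <- stats::rnorm(cfg$n_countries, 0, cfg$sigma_country)
  names(b_country) <- sprintf("C%02d", seq_len(cfg$n_countries))

  broilers <- round(stats::rlnorm(n, meanlog = log(35000), sdlog = 0.5))
  rounds <- sample(5:8, n, replace = TRUE)
  workers <- pmax(1L, round(stats::rlnorm(n, meanlog = log(2), sdlog = 0.45)))

  X <- matrix(0L, n, cfg$n_features,
              dimnames = list(NULL, cfg$feature_names))
  for (j in seq_len(cfg$n_features)) {
    X[, j] <- stats::rbinom(n, 1L, cfg$feature_prevalences[j])
  }

  beta <- stats::setNames(numeric(cfg$n_features), cfg$feature_names)
  beta[names(cfg$true_effects)] <- cfg$true_effects

  lp <- cfg$intercept +
    cfg$covariate_effects[1] * (log(broilers) - log(35000)) +
    cfg$covariate_effects[2] * (rounds - 6.5) +
    cfg$covariate_effects[3] * (log(workers) - log(2)) +
    drop(X %*% beta) +
    b_country[country]
  for (it in cfg$interaction_terms) {
    lp <- lp + it[[3]] * X[, it[[1]]] * X[, it[[2]]]
  }
  z <- lp + stats::rnorm(n, 0, cfg$sigma_noise)
  ti <- pmax(exp(z) - 1, 0)
  if (cfg$zero_inflation > 0) {
    ti[stats::runif(n) < cfg$zero_inflation] <- 0
  }

  Xdf <- as.data.frame(X)
  if (length(cfg$missing_features) && cfg$missing_rate > 0) {
    for (f in cfg$missing_features) {
      Xdf[[f]][stats::runif(n) < cfg$missing_rate] <- NA_integer_
    }
  }

  out <- data.frame(
    farm_id = sprintf("F%03d", seq_len(n)),
    country = country,
    broilers_per_round = broilers,
    rounds_per_year = rounds,
    n_workers = workers,
    tiddd = ti,
    stringsAsFactors = FALSE
  )
  cbind(out, Xdf)
}

#' Planted ground-truth main effects
#'
#' Returns the full map feature -> planted main effect (on the transformed
#' AMU scale) used by the generator, with zeros for unplanted features.
#' Recovery tests compare estimated effect signs against this table.
#'
#' @param config a [synthetic_config()].
#' @return Named numeric vector over all features.
#' @export
ground_truth <- function(config) {
  validate_synthetic_config(config)
  eff <- stats::setNames(numeric(config$n_features), config$feature_names)
  eff[names(config$true_effects)] <- config$true_effects
  eff
}

#' Planted country intercepts
#'
#' Re-draws the country random intercepts exactly as [generate_farms()] does
#' under the same seed, for parameter-recovery comparisons.
#'
#' @param config a [synthetic_config()].
#' @return Named numeric vector, one intercept per country.
#' @export
ground_truth_intercepts <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  stats::setNames(stats::rnorm(config$n_countries, 0, config$sigma_country),
                  sprintf("C%02d", seq_len(config$n_countries)))
}

#' Write / read a farm table as CSV
#'
#' Plain one-header-row CSV round-trip for farm tables; missing biosecurity
#' answers are stored as empty cells.
#'
#' @param farms a farm table from [generate_farms()] or of the same shape.
#' @param path file path.
#' @return `read_farms()` returns the farm table; `write_farms()` its path,
#'   invisibly.
#' @export
write_farms <- function(farms, path) {
  utils::write.csv(farms, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_farms
#' @export
read_farms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!all(c("country", "tiddd") %in% names(df))) {
    stop("farm CSV must contain 'country' and 'tiddd' columns")
  }
  df
}

# Names of the non-feature columns of a farm table.
farm_meta_cols <- function() {
  c("farm_id", "country", "broilers_per_round", "rounds_per_year",
    "n_workers", "tiddd")
}

# Biosecurity feature columns of a farm table.
feature_cols <- function(farms) setdiff(names(farms), farm_meta_cols())

#' Expectation table implied by the planted ground truth
#'
#' For simulated data the "biological expectation" of each measure is known
#' exactly: a planted negative effect means the measure is protective, a
#' positive one risky, and unplanted measures have no defensible expectation
#' (`unclear`). Used by recovery tests and synthetic pipeline runs.
#'
#' @param config a [synthetic_config()].
#' @return Named character vector over all features.
#' @export
expectations_from_truth <- function(config) {
  eff <- ground_truth(config)
  out <- ifelse(eff < 0, "protective", ifelse(eff > 0, "risky", "unclear"))
  stats::setNames(out, names(eff))
}
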