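test_that("default configuration yields a balanced multi-country survey", {
  farms <- generate_farms(synthetic_config(seed = 3))
  expect_equal(nrow(farms), 180L)
  expect_equal(length(unique(farms$country)), 9L)
  expect_equal(as.integer(table(farms$country)), rep(20L, 9))
  expect_true(all(farms$tiddd >= 0))
  feats <- setdiff(names(farms), c("farm_id", "country", "broilers_per_round",
                                   "rounds_per_year", "n_workers", "tiddd"))
  expect_length(feats, 53L)
  expect_true(all(unlist(farms[feats]) %in% c(0, 1)))
  expect_true(all(farms$rounds_per_year %in% 5:8))
})

test_that("generation is deterministic and degenerates as configured", {
  cfg <- synthetic_config(seed = 42)
  expect_identical(generate_farms(cfg), generate_farms(cfg))

  flat <- synthetic_config(
    true_effects = stats::setNames(numeric(0), character(0)),
    interaction_terms = list(), covariate_effects = c(0, 0, 0),
    sigma_country = 0, sigma_noise = 0, zero_inflation = 0, seed = 5)
  farms <- generate_farms(flat)
  expect_equal(length(unique(farms$tiddd)), 1L)
})

test_that("marginal prevalences and zero fraction match configuration", {
  cfg <- synthetic_config(farms_per_country = 200, zero_inflation = 0.05,
                          seed = 8)
  farms <- generate_farms(cfg)
  n <- nrow(farms)
  expect_equal(n, 1800L)
  for (j in c(1, 27, 53)) {
    p <- cfg$feature_prevalences[j]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(farms[[cfg$feature_names[j]]]) - p), 3 * se)
  }
  # exact zeros come from the inflation mechanism plus clamping of linear
  # predictors below the transform of zero; a flat configuration keeps the
  # predictor well above zero so the inflation rate can be checked alone
  flat <- synthetic_config(
    farms_per_country = 200,
    true_effects = stats::setNames(numeric(0), character(0)),
    interaction_terms = list(), covariate_effects = c(0, 0, 0),
    sigma_country = 0.5, sigma_noise = 0.5, zero_inflation = 0.05,
    seed = 8)
  zfarms <- generate_farms(flat)
  p0 <- 0.05
  expect_lt(abs(mean(zfarms$tiddd == 0) - p0),
            3 * sqrt(p0 * (1 - p0) / nrow(zfarms)))
})

test_that("between-country variance of country means matches sigma_country", {
  # oracle: empirical variance of simulated country means over replicates
  means <- unlist(lapply(1:30, function(s) {
    cfg <- synthetic_config(
      n_countries = 9, farms_per_country = 100, n_features = 4,
      true_effects = stats::setNames(numeric(0), character(0)),
      interaction_terms = list(), covariate_effects = c(0, 0, 0),
      sigma_country = 1.0, sigma_noise = 0.1, zero_inflation = 0, seed = s)
    farms <- generate_farms(cfg)
    tapply(transform_amu(farms$tiddd), farms$country, mean) - cfg$intercept
  }))
  expect_gt(var(means), 0.75)
  expect_lt(var(means), 1.25)
})

test_that("ground truth echoes the planted configuration", {
  cfg <- synthetic_config(n_features = 10,
                          true_effects = c(q_004 = -0.8),
                          interaction_terms = list())
  eff <- ground_truth(cfg)
  expect_length(eff, 10L)
  expect_equal(eff[["q_004"]], -0.8)
  expect_true(all(eff[setdiff(names(eff), "q_004")] == 0))

  exp_dir <- expectations_from_truth(cfg)
  expect_equal(unname(exp_dir["q_004"]), "protective")
  expect_true(all(exp_dir[setdiff(names(exp_dir), "q_004")] == "unclear"))
})

test_that("planted effect signs are recovered on noise-free data", {
  cfg <- small_signal_config(seed = 9, sigma_noise = 0, sigma_country = 0)
  d <- encoded_data(cfg)
  fit <- fit_mixrf(d$X, d$y, d$groups, small_mixrf_cfg(seed = 9))
  expect_lt(partial_effect(fit, d$X, "q_001"), 0)
  expect_gt(partial_effect(fit, d$X, "q_002"), 0)
})

test_that("missingness is applied at the configured rate and configs validate", {
  cfg <- synthetic_config(n_features = 10, farms_per_country = 100,
                          missing_features = c("q_001", "q_002"),
                          missing_rate = 0.10, seed = 2)
  farms <- generate_farms(cfg)
  rate <- mean(is.na(c(farms$q_001, farms$q_002)))
  expect_lt(abs(rate - 0.10), 3 * sqrt(0.1 * 0.9 / (2 * nrow(farms))))
  expect_false(anyNA(farms$q_003))

  expect_error(synthetic_config(feature_prevalences = c(0.5, 1.2),
                                n_features = 2), "\\[0, 1\\]")
  expect_error(synthetic_config(sigma_noise = -1), ">= 0")
  expect_error(synthetic_config(true_effects = c(zz_9 = 1)), "zz_9")
  expect_error(synthetic_config(zero_inflation = 2), "\\[0, 1\\]")
})

test_that("farm tables round-trip through CSV", {
  cfg <- synthetic_config(n_countries = 2, farms_per_country = 5,
                          n_features = 4, missing_features = "q_001",
                          missing_rate = 0.3, seed = 4)
  farms <- generate_farms(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_farms(farms, path)
  back <- read_farms(path)
  expect_equal(back$tiddd, farms$tiddd)
  expect_equal(back$q_001, farms$q_001)
  expect_equal(back$country, farms$country)
})
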