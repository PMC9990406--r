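test_that("imputation resolves missing levels to plausible 0/1 values", {
  X_clean <- data.frame(a = rnorm(10), q_001 = rep(0:1, 5))
  expect_identical(impute_missing_levels(X_clean), X_clean)

  # q_002 copies q_001 with high fidelity; mask 10% and recover
  set.seed(61)
  n <- 150
  q1 <- rbinom(n, 1, 0.5)
  q2 <- ifelse(runif(n) < 0.9, q1, 1 - q1)
  truth <- q2
  masked <- q2
  miss <- sample(n, 15)
  masked[miss] <- NA
  lv <- as.character(masked); lv[is.na(lv)] <- "missing"
  X <- data.frame(covar = rnorm(n), q_001 = q1,
                  q_002 = factor(lv, levels = c("0", "1", "missing")))
  imp <- impute_missing_levels(X, seed = 61)
  expect_true(all(imp$q_002 %in% c(0, 1)))
  acc <- mean(imp$q_002[miss] == truth[miss])
  majority <- max(mean(truth[miss] == 1), mean(truth[miss] == 0))
  expect_gt(acc, majority)
  expect_identical(imp, impute_missing_levels(X, seed = 61))  # deterministic

  X_all_missing <- data.frame(
    a = rnorm(4), q_001 = factor(rep("missing", 4),
                                 levels = c("0", "1", "missing")))
  expect_error(impute_missing_levels(X_all_missing), "entirely missing")
})

test_that("partial dependence equals its brute-force definition", {
  cfg <- small_signal_config(seed = 71, farms_per_country = 15)
  d <- encoded_data(cfg)
  fit <- fit_mixrf(d$X, d$y, d$groups, small_mixrf_cfg(seed = 71))
  for (f in c("q_001", "q_003")) {
    # independent oracle: per-farm counterfactual predictions straight from
    # the underlying forest, averaged explicitly
    preds1 <- preds0 <- numeric(nrow(d$X))
    for (i in seq_len(nrow(d$X))) {
      row1 <- d$X[i, ]; row1[[f]] <- 1
      row0 <- d$X[i, ]; row0[[f]] <- 0
      preds1[i] <- predict(fit$forest, data = row1,
                           num.threads = 1)$predictions
      preds0[i] <- predict(fit$forest, data = row0,
                           num.threads = 1)$predictions
    }
    expect_equal(partial_effect(fit, d$X, f), mean(preds1) - mean(preds0),
                 tolerance = 1e-12)
  }
  expect_error(partial_effect(fit, d$X, "nope"), "unknown")
})

test_that("planted effects are recovered with the right sign", {
  signs <- vapply(1:10, function(s) {
    cfg <- small_signal_config(seed = 200 + s, farms_per_country = 20,
                               sigma_noise = 0.2)
    d <- encoded_data(cfg)
    fit <- fit_mixrf(d$X, d$y, d$groups, small_mixrf_cfg(seed = s))
    c(partial_effect(fit, d$X, "q_001") < 0,
      partial_effect(fit, d$X, "q_002") > 0)
  }, logical(2))
  expect_gte(mean(signs), 0.95)
})

test_that("a constant feature still yields a computable effect", {
  cfg <- small_signal_config(seed = 73, farms_per_country = 10)
  d <- encoded_data(cfg)
  X <- d$X; X$q_001 <- 1   # forced constant
  fit <- fit_mixrf(X, d$y, d$groups, small_mixrf_cfg(seed = 73))
  expect_true(is.finite(partial_effect(fit, X, "q_001")))
})

test_that("bootstrap CIs are percentile intervals, ordered and reproducible", {
  cfg <- small_signal_config(seed = 81, farms_per_country = 12)
  d <- encoded_data(cfg)
  ci <- bootstrap_ci(d$X, d$y, d$groups, "q_001", n_boot = 20, seed = 81,
                     mixrf_cfg = small_mixrf_cfg(seed = 81, n_trees = 30))
  expect_lte(ci$ci_low, ci$ci_high)
  expect_equal(unname(c(ci$ci_low, ci$ci_high)),
               unname(quantile(ci$boot_effects, c(0.025, 0.975))))
  ci2 <- bootstrap_ci(d$X, d$y, d$groups, "q_001", n_boot = 20, seed = 81,
                      mixrf_cfg = small_mixrf_cfg(seed = 81, n_trees = 30))
  expect_identical(ci$boot_effects, ci2$boot_effects)
  expect_error(bootstrap_ci(d$X, d$y, d$groups, "q_001", n_boot = 5),
               ">= 10")
})

test_that("strength/weakness classification covers the full cross table", {
  effects <- c(f_pos = 0.3, f_neg = -0.3)
  grid <- expand.grid(value = c(0, 1), feature = names(effects),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- stats::setNames(grid$value[i], grid$feature[i])
    res <- classify_measures(v, effects)
    e <- effects[[grid$feature[i]]]
    expected <- if ((grid$value[i] == 1 && e < 0) ||
                    (grid$value[i] == 0 && e > 0)) "strength" else "weakness"
    expect_identical(res$label, expected)
  }
  expect_warning(out <- classify_measures(c(f0 = 1), c(f0 = 0)), "skipped")
  expect_equal(nrow(out), 0L)
  expect_error(classify_measures(c(f_pos = 0.5), effects), "0/1")
})

test_that("biological-expectation filtering keeps only matching weaknesses", {
  classified <- classify_measures(
    c(hygiene_lock = 0, vaccination_protocol_non_official = 1,
      open_water_storage = 0, two_plus_depopulation_steps = 1),
    c(hygiene_lock = -0.4, vaccination_protocol_non_official = 0.5,
      open_water_storage = -0.2, two_plus_depopulation_steps = 0.6))
  expect_setequal(classified$feature[classified$label == "weakness"],
                  c("hygiene_lock", "vaccination_protocol_non_official",
                    "open_water_storage", "two_plus_depopulation_steps"))
  expectations <- c(hygiene_lock = "protective",
                    vaccination_protocol_non_official = "protective",
                    two_plus_depopulation_steps = "risky")
  expect_warning(kept <- filter_by_expectation(classified, expectations),
                 "open_water_storage")
  # hygiene lock: negative effect, protective -> kept; vaccination protocol:
  # positive effect against protective expectation -> dropped (reverse
  # causality guard); no expectation -> dropped
  expect_setequal(kept$feature,
                  c("hygiene_lock", "two_plus_depopulation_steps"))

  unclear <- c(hygiene_lock = "unclear",
               vaccination_protocol_non_official = "unclear",
               open_water_storage = "unclear",
               two_plus_depopulation_steps = "unclear")
  expect_equal(nrow(filter_by_expectation(classified, unclear)), 0L)
})

test_that("expectation tables read from YAML and validate directions", {
  path <- system.file("extdata", "expectations_example.yaml",
                      package = "amuplan")
  exp_tab <- read_expectations(path)
  expect_identical(unname(exp_tab["hygiene_lock"]), "protective")
  expect_identical(unname(exp_tab["two_plus_depopulation_steps"]), "risky")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("f1: sometimes", bad)
  expect_error(read_expectations(bad), "invalid direction")
})
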