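test_that("a single country reduces the model to an ordinary forest", {
  set.seed(10)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                            dimnames = list(NULL, paste0("x", 1:5))))
  y <- X$x1 + rnorm(n, 0, 0.2)
  cfg <- small_mixrf_cfg(seed = 10, n_trees = 100)
  fit <- fit_mixrf(X, y, rep("only", n), cfg)
  expect_identical(fit$sigma2_b, 0)
  expect_equal(unname(fit$random_intercepts), 0)

  plain <- ranger::ranger(x = X, y = y, num.trees = 100,
                          mtry = amuplan::default_mtry(5),
                          num.threads = 1, seed = 10)
  expect_equal(predict(fit, X, include_random = FALSE),
               predict(plain, data = X, num.threads = 1)$predictions,
               tolerance = 1e-12)
})

test_that("country intercepts are recovered on planted data", {
  cfg <- small_signal_config(seed = 21, farms_per_country = 40,
                             sigma_noise = 0.2)
  d <- encoded_data(cfg)
  fit <- fit_mixrf(d$X, d$y, d$groups, small_mixrf_cfg(seed = 21,
                                                       n_trees = 100))
  truth <- ground_truth_intercepts(cfg)
  expect_named(fit$random_intercepts, names(truth))
  expect_gt(cor(fit$random_intercepts[names(truth)], truth), 0.9)
  expect_true(all(is.finite(fit$em_trace)))
  expect_gte(fit$sigma2_b, 0)
  expect_gte(fit$sigma2_e, 0)
})

test_that("duplicated farms get identical fitted values", {
  cfg <- small_signal_config(seed = 6, farms_per_country = 10)
  d <- encoded_data(cfg)
  X2 <- rbind(d$X, d$X[1, ])
  y2 <- c(d$y, d$y[1])
  g2 <- c(d$groups, d$groups[1])
  fit <- fit_mixrf(X2, y2, g2, small_mixrf_cfg(seed = 6))
  p <- predict(fit, X2, g2)
  expect_equal(p[1], p[length(p)])
})

test_that("prediction handles unknown countries and guards columns", {
  cfg <- small_signal_config(seed = 2, farms_per_country = 10)
  d <- encoded_data(cfg)
  fit <- fit_mixrf(d$X, d$y, d$groups, small_mixrf_cfg(seed = 2))
  p_unknown <- predict(fit, d$X[1:3, ], groups = rep("ZZ", 3))
  p_none <- predict(fit, d$X[1:3, ], include_random = FALSE)
  expect_equal(p_unknown, p_none)
  p_known <- predict(fit, d$X[1:3, ], groups = d$groups[1:3])
  expect_equal(p_known - p_none,
               unname(fit$random_intercepts[d$groups[1:3]]))
  expect_error(predict(fit, d$X[, rev(names(d$X))]), "columns")
})

test_that("Gini importance is normalised and zero for unused features", {
  cfg <- small_signal_config(seed = 13, farms_per_country = 15)
  d <- encoded_data(cfg)
  X <- d$X
  X$constant <- 1   # no split on a constant column is ever possible
  fit <- fit_mixrf(X, d$y, d$groups, small_mixrf_cfg(seed = 13))
  imp <- gini_importance(fit)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
  expect_equal(unname(imp["constant"]), 0)
})

test_that("a strongly planted feature ranks first among noise features", {
  hits <- vapply(1:10, function(s) {
    cfg <- synthetic_config(
      n_countries = 3, farms_per_country = 30, n_features = 10,
      true_effects = c(q_005 = 1.5), interaction_terms = list(),
      covariate_effects = c(0, 0, 0), sigma_country = 0,
      sigma_noise = 0.2, zero_inflation = 0, seed = 100 + s)
    d <- encoded_data(cfg)
    fit <- fit_mixrf(d$X[, d$retained], d$y, d$groups,
                     small_mixrf_cfg(seed = s))
    names(which.max(gini_importance(fit))) == "q_005"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("proximities are symmetric, unit-diagonal tree-count fractions", {
  cfg <- small_signal_config(seed = 17, farms_per_country = 8)
  d <- encoded_data(cfg)
  X2 <- rbind(d$X, d$X[1, ])   # duplicate of farm 1
  cfg_rf <- small_mixrf_cfg(seed = 17, n_trees = 40)
  fit <- fit_mixrf(X2, c(d$y, d$y[1]), c(d$groups, d$groups[1]), cfg_rf)
  P <- rf_proximity(fit, X2)
  expect_true(isSymmetric(unname(unclass(P))))
  expect_equal(diag(P), rep(1, nrow(X2)))
  expect_true(all(P >= 0 & P <= 1))
  counts <- unclass(P) * 40
  expect_equal(counts, round(counts), tolerance = 1e-9)  # multiples of 1/40
  expect_equal(P[1, nrow(X2)], 1)                        # twin farms
})

test_that("proximity matches a brute-force co-leaf count on a toy forest", {
  set.seed(30)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  y <- X$a + rnorm(12, 0, 0.1)
  fit <- fit_mixrf(X, y, rep("g", 12),
                   mixrf_config(n_trees = 3, mtry = 1, max_em_iter = 1,
                                seed = 30))
  P <- rf_proximity(fit, X)
  nodes <- predict(fit$forest, data = X, type = "terminalNodes",
                   num.threads = 1)$predictions
  # independent oracle: explicit double loop over farm pairs and trees
  for (i in 1:12) for (j in 1:12) {
    expect_equal(P[i, j], sum(nodes[i, ] == nodes[j, ]) / 3)
  }
})

test_that("degenerate outcomes are flagged", {
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_warning(fit_mixrf(X, rep(1, 20), rep(c("A", "B"), 10),
                           small_mixrf_cfg()), "constant")
  expect_error(fit_mixrf(X, rnorm(10), rep("A", 20), small_mixrf_cfg()),
               "matching")
})
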