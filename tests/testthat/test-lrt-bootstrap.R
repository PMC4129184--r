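test_that("the statistic reduces to closed-form likelihood arithmetic", {
  # identical models: Lambda = 0
  y <- rbinom(100, 1, 0.5)
  f <- fit_glm(y, matrix(1, 100, 1))
  expect_equal(lambda_statistic(f, f), 0)

  # 2x2 layout, rates 0.9 vs 0.1, 100 observations per arm, no confounder
  d <- two_arm_data(100, 100, 90, 10)
  f0 <- fit_glm(d$y, matrix(1, 200, 1))
  f1 <- fit_glm(d$y, cbind(1 - d$z, d$z))
  lam <- lambda_statistic(f1, f0)
  expect_equal(lam, closed_form_gain(90, 100, 10, 100), tolerance = 1e-6)
  # Lambda equals the deviance difference
  expect_equal(lam, f0$deviance - f1$deviance, tolerance = 1e-10)
  # grossly non-nested logliks raise
  f_bad <- list(loglik = f1$loglik - 5)
  expect_error(lambda_statistic(f_bad, f1), "negative")
})

test_that("moment matching solves the two scaled chi-squared equations", {
  # a sample engineered to have mean 4 and variance 8 -> m = 1, b = 4
  x <- c(2, 6)               # mean 4, var 8
  mb <- moment_match_scaled_chisq(x)
  expect_equal(mb$m, 1)
  expect_equal(mb$b, 4)
  # scale equivariance: samples * c -> m / c, b unchanged
  mb2 <- moment_match_scaled_chisq(3 * x)
  expect_equal(mb2$m, 1 / 3)
  expect_equal(mb2$b, 4)
  expect_error(moment_match_scaled_chisq(rep(2, 10)), "variance")
  expect_error(moment_match_scaled_chisq(1), "two")
})

test_that("moment matching recovers chi-squared parameters from draws", {
  for (k in c(1, 3, 5)) {
    set.seed(100 + k)
    mb <- moment_match_scaled_chisq(rchisq(10000, df = k))
    expect_gt(mb$m, 0.9); expect_lt(mb$m, 1.1)
    expect_gt(mb$b, k * 0.9); expect_lt(mb$b, k * 1.1)
  }
})

test_that("p-values follow the scaled chi-squared survival function", {
  # chisq(2) closed form: p = exp(-Lambda / 2) at m = 1
  lam <- 2 * log(2)
  expect_equal(pchisq(1 * lam, df = 2, lower.tail = FALSE), 0.5,
               tolerance = 1e-12)
  # monotone decreasing in Lambda for fixed (m, b)
  lams <- seq(0, 10, by = 0.5)
  ps <- pchisq(1.3 * lams, df = 2.7, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  expect_equal(ps[1], 1)
})

test_that("bootstrap statistics are reproducible and honor B", {
  d <- generate_scenario(1, n = 400, seed = 81)
  b0 <- bootstrap_null(d$y, d$X, d$Z, j = 2, B = 0)
  expect_length(b0, 0)
  ctl <- pltr_control(min_node_size = 30)
  b1 <- bootstrap_null(d$y, d$X, d$Z, j = 2, B = 8, control = ctl, seed = 5)
  b2 <- bootstrap_null(d$y, d$X, d$Z, j = 2, B = 8, control = ctl, seed = 5)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_true(all(b1 >= 0))
})

test_that("root selections short-circuit to p = 1", {
  d <- generate_scenario(1, n = 600, seed = 82)
  fit <- fit_pltr(d$y, d$X, d$Z)
  sq <- build_sequence(d$y, d$X, fit$tree, d$Z, 5)
  sel <- select_by_criterion(sq, "bic")
  # force the root if BIC happened to pick structure on this draw
  sel$selected_j <- 1L
  t1 <- pltr_test(d$y, d$X, d$Z, sel, B = 10, seed = 1)
  expect_equal(t1$p_value, 1)
  expect_equal(t1$lambda_obs, 0)
})

test_that("the full test composes its parts and is calibrated on null data", {
  ctl <- pltr_control(min_node_size = 25)
  d <- generate_scenario(1, n = 300, seed = 83)
  fit <- fit_pltr(d$y, d$X, d$Z, ctl)
  sq <- build_sequence(d$y, d$X, fit$tree, d$Z, 3, ctl)
  sel <- select_by_criterion(sq, "aic")  # aic picks structure more often
  res <- pltr_test(d$y, d$X, d$Z, sel, B = 60, control = ctl, seed = 9)
  if (sel$selected_j > 1) {
    expect_equal(res$p_value,
                 pchisq(res$m * res$lambda_obs, res$b, lower.tail = FALSE))
    expect_equal(res$lambda_obs,
                 lambda_statistic(sq$models[[sel$selected_j]], sq$models[[1]]),
                 tolerance = 1e-10)
    mb <- moment_match_scaled_chisq(res$boot_lambdas)
    expect_equal(mb$m, res$m)
    expect_equal(mb$b, res$b)
  }

  # type-I error at nominal 0.05 over null replicates (fixed j = 2 test)
  rej <- vapply(1:40, function(s) {
    dd <- generate_scenario(1, n = 300, seed = 8300 + s)
    ff <- fit_pltr(dd$y, dd$X, dd$Z, ctl)
    if (n_leaves(ff$tree) < 2) return(NA)
    ss <- build_sequence(dd$y, dd$X, ff$tree, dd$Z, 2, ctl)
    lam <- lambda_statistic(ss$models[[2]], ss$models[[1]])
    boot <- bootstrap_null(dd$y, dd$X, dd$Z, 2, B = 40, ctl, seed = 8400 + s)
    mb <- moment_match_scaled_chisq(boot)
    pchisq(mb$m * lam, mb$b, lower.tail = FALSE) < 0.05
  }, NA)
  rate <- mean(rej, na.rm = TRUE)
  expect_gte(rate, 0.0); expect_lte(rate, 0.15)
})

test_that("the fitted scaled law beats the naive chi-squared on bootstrap draws", {
  # Kolmogorov distance of the bootstrap sample to its moment-matched scaled
  # chi-squared versus to the naive chisq(j - 1)
  ctl <- pltr_control(min_node_size = 25)
  wins <- vapply(1:12, function(s) {
    d <- generate_scenario(1, n = 300, seed = 8500 + s)
    boot <- bootstrap_null(d$y, d$X, d$Z, j = 3, B = 50, ctl,
                           seed = 8600 + s)
    mb <- moment_match_scaled_chisq(boot)
    ks_scaled <- ks_dist(boot, function(q) pchisq(mb$m * q, mb$b))
    ks_naive <- ks_dist(boot, function(q) pchisq(q, 2))
    ks_scaled < ks_naive
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
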