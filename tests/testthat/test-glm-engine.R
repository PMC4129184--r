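test_that("intercept-only fit returns the logit of the sample mean", {
  y <- rep(c(1, 0), c(3, 7))
  f <- fit_glm(y, matrix(1, 10, 1))
  expect_equal(unname(f$coefficients), qlogis(0.3), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("a saturating offset drives the intercept toward zero", {
  set.seed(42)
  n <- 20000
  eta <- rnorm(n, 0, 1.2)
  y <- rbinom(n, 1, plogis(eta))
  f <- fit_glm(y, matrix(1, n, 1), offset = eta)
  expect_lt(abs(unname(f$coefficients)), 0.05)
})

test_that("small-problem fits match a grid-search likelihood oracle", {
  # 8 printed toy rows, two columns (interior maximum)
  y <- c(0, 1, 1, 0, 1, 0, 1, 0)
  X <- cbind(1, c(0.5, -1, 1.5, 0.2, -0.7, -1.2, 0.9, 0.1))
  f <- fit_glm(y, X)
  oracle <- grid_glm_oracle(y, X)
  expect_lt(abs(f$loglik - oracle$loglik), 1e-4)
  expect_equal(unname(f$coefficients), oracle$coefficients, tolerance = 0.05)

  # random small problems, zero and nonzero offsets
  for (s in 1:5) {
    set.seed(s)
    n <- 8
    X1 <- matrix(rnorm(n), n, 1)
    off <- if (s %% 2) rep(0, n) else rnorm(n, 0, 0.5)
    y1 <- rbinom(n, 1, 0.5)
    if (length(unique(y1)) < 2) next
    f1 <- fit_glm(y1, X1, offset = off)
    o1 <- grid_glm_oracle(y1, X1, off, lo = -6, hi = 6, step = 0.005)
    expect_lt(abs(f1$loglik - o1$loglik), 1e-4)
  }
})

test_that("fit agrees with stats::glm on moderately sized problems", {
  set.seed(7)
  n <- 300
  X <- cbind(1, rbinom(n, 1, 0.4), rnorm(n))
  off <- rnorm(n, 0, 0.3)
  y <- rbinom(n, 1, plogis(X %*% c(-0.5, 0.8, 0.3)))
  f <- fit_glm(y, X, offset = off)
  g <- glm(y ~ 0 + X + offset(off), family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-5)
  expect_equal(f$deviance, deviance(g), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("binomial deviance follows the closed formula and never NaNs", {
  expect_equal(binomial_deviance(c(1, 0), c(0.5, 0.5)), -4 * log(0.5),
               tolerance = 1e-12)
  y <- c(1, 0, 1)
  expect_lt(binomial_deviance(y, clamp_mu <- pmin(pmax(y, 1e-10), 1 - 1e-10)),
            1e-7)
  # term-wise oracle on random values
  set.seed(3)
  yy <- rbinom(50, 1, 0.5)
  mm <- runif(50, 0.05, 0.95)
  oracle <- -2 * sum(ifelse(yy == 1, log(mm), log(1 - mm)))
  expect_equal(binomial_deviance(yy, mm), oracle, tolerance = 1e-10)
  # conflicting pure prediction: finite, no NaN
  expect_true(is.finite(binomial_deviance(c(1, 0), c(1e-15, 1))))
})

test_that("deviance is nonincreasing when a design column is appended", {
  set.seed(11)
  for (s in 1:5) {
    n <- 60
    X1 <- matrix(rnorm(2 * n), n, 2)
    y <- rbinom(n, 1, 0.4)
    d1 <- fit_glm(y, cbind(1, X1[, 1]))$deviance
    d2 <- fit_glm(y, cbind(1, X1))$deviance
    expect_lte(d2, d1 + 1e-8)
  }
})

test_that("adding a constant to the offset shifts the intercept by its negative", {
  set.seed(5)
  n <- 200
  X <- cbind(1, rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.4)
  f0 <- fit_glm(y, X)
  f1 <- fit_glm(y, X, offset = rep(1.5, n))
  expect_equal(unname(f1$coefficients[1]), unname(f0$coefficients[1]) - 1.5,
               tolerance = 1e-6)
  expect_equal(unname(f1$coefficients[2]), unname(f0$coefficients[2]),
               tolerance = 1e-6)
})

test_that("perfect separation yields a capped, flagged fit instead of an error", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(1, y)       # separating column
  f <- fit_glm(y, X)
  expect_false(f$converged)
  expect_true(all(abs(f$linear_predictor) <= 30 + 1e-9))
  expect_true(all(f$fitted_means > 0 & f$fitted_means < 1))
})

test_that("dimension mismatches raise input errors", {
  expect_error(fit_glm(c(0, 1), matrix(1, 3, 1)), "row count")
  expect_error(fit_glm(c(0, 1), matrix(1, 2, 1), offset = 1:3), "length")
  expect_error(fit_glm(c(0, 2), matrix(1, 2, 1)), "binary")
})
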