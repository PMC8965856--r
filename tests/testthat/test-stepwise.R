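test_that("stepwise selection recovers an exact linear dependence", {
  set.seed(101)
  X <- data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20),
                  x4 = rnorm(20), x5 = rnorm(20))
  y <- 25 * X$x1
  ## noise-free outcome: summary.lm warns about the perfect fit
  fit <- suppressWarnings(stepwise_regression(y, X))
  expect_identical(fit$selected, "x1")
  expect_lt(abs(fit$table$B_selected[fit$table$predictor == "x1"] - 25), 1e-6)
  expect_equal(sum(fit$table$selected), 1L)
  expect_equal(fit$trace[[1]]$variable, "x1")
})

test_that("p_enter = p_remove = 1 reproduces the full-entry OLS fit", {
  set.seed(102)
  X <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  y <- 2 + X$a - 0.5 * X$b + rnorm(15)
  fit <- stepwise_regression(y, X, p_enter = 1, p_remove = 1)
  expect_setequal(fit$selected, names(X))
  ref <- lm(y ~ a + b + c, data = X)
  expect_equal(sort(coef(fit$fit_selected)), sort(coef(ref)), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(ref)$r.squared)
  expect_equal(fit$table$B_selected[order(fit$table$predictor)],
               fit$table$B_full[order(fit$table$predictor)])
})

test_that("rank deficiency is reported with the offending column", {
  set.seed(103)
  X <- data.frame(u = rnorm(20), v = rnorm(20))
  X$w <- 2 * X$u
  expect_error(stepwise_regression(rnorm(20), X), "rank-deficient.*w")
  expect_error(stepwise_regression(rnorm(4), X[1:4, ]), "n > number of candidates")
})

test_that("forward entry false-positive rate under the global null is near 1 - 0.95^5", {
  set.seed(104)
  n_sim <- 400
  any_entered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    X <- data.frame(matrix(rnorm(20 * 5), 20, 5))
    y <- rnorm(20)
    any_entered[i] <- length(stepwise_regression(y, X)$selected) > 0
  }
  rate <- mean(any_entered)
  expect_gt(rate, 0.12)   # 1 - 0.95^5 = 0.226; wide band for simulation noise
  expect_lt(rate, 0.33)
})

test_that("removal drops a predictor whose contribution collapses", {
  # x2 is a noisy proxy of x1: once x1 enters, x2's partial p rises above
  # the removal threshold in a forced entry order.
  set.seed(105)
  x1 <- rnorm(40)
  x2 <- x1 + rnorm(40, sd = 0.4)
  y <- 3 * x1 + rnorm(40, sd = 0.5)
  fit <- stepwise_regression(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(fit$selected, "x1")
  acts <- vapply(fit$trace, `[[`, character(1), "action")
  expect_true(all(acts %in% c("enter", "remove")))
})
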