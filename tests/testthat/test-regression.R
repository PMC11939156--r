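test_that("descriptive statistics follow the stated conventions", {
  d <- descriptive_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$sd, 1)
  expect_equal(descriptive_stats(c(1, 2, 3, 4))$median, 2.5)
  d <- descriptive_stats(c(5, 5, 5))
  expect_equal(d$sd, 0)
  expect_equal(c(d$min, d$max), c(5, 5))
  d1 <- descriptive_stats(7)
  expect_equal(d1$sd, 0)
  expect_false(d1$sd_defined)
  expect_error(descriptive_stats(numeric(0)), "at least one")
})

test_that("simple OLS recovers exact and hand-computed fits", {
  x <- 1:5
  # exact line: R warns that the F test is unreliable, which is expected
  fit <- suppressWarnings(fit_simple_ols(x, 2 * x + 1))
  expect_equal(fit$b0, 1)
  expect_equal(fit$b1, 2)
  expect_equal(fit$ss_residual, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  fit <- fit_simple_ols(c(1, 2, 3), c(1, 3, 2))
  expect_equal(fit$b1, 0.5)
  expect_equal(fit$b0, 1.0)
  expect_error(fit_simple_ols(c(2, 2, 2), c(1, 2, 3)),
               "degenerate predictor")
  expect_error(fit_simple_ols(1:4, 1:3), "equal length")
  expect_error(fit_simple_ols(1:2, 1:2), "n >= 3")
})

test_that("OLS matches the closed-form and grid-minimisation oracles", {
  set.seed(41)
  for (rep in 1:5) {
    x <- runif(12, 0, 10)
    y <- 1.5 + 0.8 * x + rnorm(12)
    fit <- fit_simple_ols(x, y)
    closed <- oracle_ols_closed(x, y)
    expect_equal(fit$b0, unname(closed["b0"]), tolerance = 1e-10)
    expect_equal(fit$b1, unname(closed["b1"]), tolerance = 1e-10)
  }
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 5, 6, 9)
  fit <- fit_simple_ols(x, y)
  grid <- oracle_ols_grid(x, y, fit$b0 + c(-1, 1), fit$b1 + c(-1, 1))
  expect_equal(fit$b0, unname(grid["b0"]), tolerance = 0.01)
  expect_equal(fit$b1, unname(grid["b1"]), tolerance = 0.01)
})

test_that("the regression report satisfies its internal identities", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    x <- rnorm(n, 5, 2)
    y <- 1 + 0.5 * x + rnorm(n, 0, 2)
    f <- fit_simple_ols(x, y)
    expect_equal(f$ss_regression + f$ss_residual, f$ss_total,
                 tolerance = 1e-8)
    expect_equal(f$f_stat, f$t_b1^2, tolerance = 1e-8)
    expect_equal(f$standardized_beta, sign(f$b1) * sqrt(f$r_squared),
                 tolerance = 1e-8)
    expect_equal(f$p_f, f$p_b1, tolerance = 1e-12)
    # fitted line passes through the mean point
    expect_equal(f$b0 + f$b1 * mean(x), mean(y), tolerance = 1e-10)
    expect_equal(f$df_residual, n - 2L)
  }
})

test_that("two-sided p-values behave like a central t tail", {
  expect_equal(two_sided_p(0, 10), 1)
  expect_lt(two_sided_p(100, 10), 1e-10)
  expect_lt(abs(two_sided_p(2.4085, 35) - 0.0215), 0.0005)
  expect_error(two_sided_p(1, 0), "degrees of freedom")
  # monotone decreasing in |t|, symmetric in sign
  ts <- seq(0, 5, by = 0.25)
  ps <- two_sided_p(ts, 7)
  expect_true(all(diff(ps) < 0))
  expect_equal(two_sided_p(-2, 7), two_sided_p(2, 7))
})

test_that("published coefficient table is internally consistent", {
  # slope and intercept t statistics recomputed from the printed pairs
  expect_lt(abs(1.881 / 0.781 - 2.408), 0.001)
  expect_lt(abs(0.399 / 4.407 - 0.090), 0.001)
  # the slope p-value follows from the t distribution with df = n - 2 = 35
  expect_lt(abs(two_sided_p(1.881 / 0.781, 35) - 0.021), 0.001)
})

test_that("validation reports flag significance and degenerate inputs", {
  x <- seq(1, 10, length.out = 20)
  rep <- suppressWarnings(validation_report(x, 0.399 + 1.881 * x))
  expect_equal(rep$ols$r_squared, 1, tolerance = 1e-10)
  expect_lt(rep$ols$p_b1, 1e-10)
  expect_true(rep$slope_significant)
  expect_error(validation_report(c(1, 2), c(3, 4)), "n >= 3")
  flat <- report_fields(rep)
  expect_equal(flat$b1, 1.881, tolerance = 1e-9)
  expect_equal(flat$n, 20)
})
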