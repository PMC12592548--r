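# Intervention regression and its closed-form OLS oracle.

ols_oracle <- function(y, d) {
  # hand-rolled group-means closed form for a single 0/1 regressor
  list(intercept = mean(y[d == 0]),
       coef = mean(y[d == 1]) - mean(y[d == 0]))
}

test_that("a noise-free step outcome is recovered exactly", {
  keys <- cohort_window(1995, 1, 60)
  d <- monthly_series(rep(c(0, 1), c(54, 6)), keys, "dummy")
  y <- monthly_series(0.02 + 0.05 * as.numeric(d), keys, "outcome")
  fit <- suppressWarnings(fit_intervention(y, d, error_model = "iid"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.02, tolerance = 1e-12)
  expect_equal(co$estimate[co$term == "dummy"], 0.05, tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
})

test_that("OLS matches the group-means oracle exactly", {
  set.seed(1)
  for (i in 1:5) {
    n <- 288
    d <- rep(0, n); d[sample(n, 7)] <- 1
    y <- 0.017 + 0.044 * d + rnorm(n, 0, 0.035)
    keys <- cohort_window(1995, 1, n)
    fit <- fit_intervention(monthly_series(y, keys, "y"),
                            monthly_series(d, keys, "d"),
                            error_model = "iid")
    or <- ols_oracle(y, d)
    co <- fit$coefficients
    expect_equal(co$estimate[co$term == "dummy"], or$coef, tolerance = 1e-12)
    expect_equal(co$estimate[co$term == "(Intercept)"], or$intercept,
                 tolerance = 1e-12)
    # T statistics are estimate over SE by construction
    expect_equal(co$t, co$estimate / co$se, tolerance = 1e-12)
  }
})

test_that("swapping minuend and subtrahend flips every coefficient", {
  set.seed(2)
  keys <- cohort_window(1995, 1, 120)
  a <- monthly_series(rnorm(120, 0.34, 0.03), keys, "a")
  b <- monthly_series(rnorm(120, 0.32, 0.03), keys, "b")
  d <- monthly_series(rep(c(0, 1, 0), c(50, 6, 64)), keys, "d")
  f1 <- fit_intervention(risk_difference(a, b), d, error_model = "iid")
  f2 <- fit_intervention(risk_difference(b, a), d, error_model = "iid")
  expect_equal(f1$coefficients$estimate, -f2$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-12)
})

test_that("degenerate designs are refused", {
  keys <- cohort_window(1995, 1, 40)
  y <- monthly_series(rnorm(40), keys, "y")
  d_const <- monthly_series(rep(0, 40), keys, "d")
  expect_error(fit_intervention(y, d_const), "constant")
  d_mis <- monthly_series(rep(c(0, 1), 20), cohort_window(1996, 1, 40), "d")
  expect_error(fit_intervention(y, d_mis), "not aligned")
})

test_that("autocorrelated outcomes are escalated to ARMA errors", {
  set.seed(3)
  keys <- cohort_window(1995, 1, 288)
  d <- rep(0, 288); d[sample(288, 7)] <- 1
  base <- as.numeric(arima.sim(list(ar = 0.8), n = 288, sd = 0.02))
  y <- monthly_series(0.02 + 0.05 * d + base, keys, "y")
  fit <- fit_intervention(y, monthly_series(d, keys, "d"))
  expect_identical(fit$error_model, "arma")
  expect_false(is.null(fit$error_spec))
  co <- fit$coefficients
  est <- co$estimate[co$term == "dummy"]
  se <- co$se[co$term == "dummy"]
  expect_lt(abs(est - 0.05), 2.5 * se)
  # iid path would be chosen for a white outcome
  y2 <- monthly_series(0.02 + 0.05 * d + rnorm(288, 0, 0.02), keys, "y")
  expect_identical(fit_intervention(y2, monthly_series(d, keys, "d"))$error_model,
                   "iid")
})

test_that("support follows the 1.96 SE rule in the hypothesized direction", {
  keys <- cohort_window(1995, 1, 200)
  d <- monthly_series(rep(c(0, 1, 0), c(90, 8, 102)), keys, "d")
  set.seed(4)
  y_strong <- monthly_series(0.02 + 0.06 * as.numeric(d) + rnorm(200, 0, 0.01),
                             keys, "y")
  f <- fit_intervention(y_strong, d, error_model = "iid")
  expect_true(f$support)
  # same data, opposite hypothesized direction: not supported
  f_neg <- fit_intervention(y_strong, d, error_model = "iid",
                            direction = "negative")
  expect_false(f_neg$support)
})

test_that("robustness outcome recovers a negative planted effect", {
  cfg <- sim_config(n_months = 144L, outlier_months = c(20L, 45L, 70L, 95L, 120L),
                    delta = 0.08)
  sim <- simulate_records(cfg, seed = 41)
  tab <- build_cohort_table(filter_records(sim$records)$records, seed = 42,
                            n_months = 144L)
  ratio <- stillbirth_sex_ratio(tab)
  f <- select_model(ratio)
  o <- detect_high_outliers(f, mode = "simple")
  # use the known truth as the dummy so the check isolates the regression
  o$flagged <- sim$truth$outlier_keys
  o$flagged_idx <- sim$truth$outlier_months
  rob <- robustness_male_female(tab, o)
  co <- rob$coefficients
  est <- co$estimate[co$term == "dummy"]
  se <- co$se[co$term == "dummy"]
  expect_lt(est, 0)
  # attenuation from cohort re-randomization keeps the estimate between
  # the full planted effect and about half of it
  expect_lt(abs(est - (-0.08)), max(0.05, 3 * se))
  expect_equal(attr(rob, "outcome_mean"), mean(risk_difference(
    neonatal_risk(tab, "NHB", "M"), neonatal_risk(tab, "NHB", "F"))))
})

test_that("continuous covariate leaves the dummy estimate almost unchanged", {
  set.seed(5)
  keys <- cohort_window(1995, 1, 288)
  d <- rep(0, 288); d[sample(288, 7)] <- 1
  y <- monthly_series(0.017 + 0.044 * d + rnorm(288, 0, 0.035), keys, "y")
  dev <- monthly_series(rnorm(288, 0, 0.14), keys, "dev")
  dm <- monthly_series(d, keys, "d")
  f1 <- fit_intervention(y, dm, error_model = "iid")
  f2 <- continuous_null_check(y, dm, dev, error_model = "iid")
  c1 <- f1$coefficients$estimate[f1$coefficients$term == "dummy"]
  c2 <- f2$coefficients$estimate[f2$coefficients$term == "dummy"]
  se <- f1$coefficients$se[f1$coefficients$term == "dummy"]
  expect_lt(abs(c1 - c2), 0.5 * se)
  # the pure-noise deviation term is itself null
  cdev <- f2$coefficients[f2$coefficients$term == "deviation", ]
  expect_lt(abs(cdev$estimate), 2 * cdev$se)
})

test_that("a deviation series collinear with the dummy is refused", {
  keys <- cohort_window(1995, 1, 100)
  d <- monthly_series(rep(c(0, 1), c(90, 10)), keys, "d")
  y <- monthly_series(rnorm(100), keys, "y")
  dev <- monthly_series(2 * as.numeric(d), keys, "dev")
  expect_error(continuous_null_check(y, d, dev, error_model = "iid"),
               "collinear")
})
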