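# Intervention (dummy-variable) regression of a risk-difference series on
# the high-stillbirth indicator, with classical inference. When the outcome
# series itself shows no autocorrelation (Ljung-Box), the regression is
# ordinary least squares with homoskedastic SEs; otherwise it is embedded in
# the AIC-selected ARMA error structure of the outcome.

# sparse ARMA regression with external regressors via stats::arima
fit_arma_regression <- function(y, X, spec) {
  p <- if (length(spec$ar_lags)) max(spec$ar_lags) else 0L
  q <- if (length(spec$ma_lags)) max(spec$ma_lags) else 0L
  fixed <- c(
    ifelse(seq_len(p) %in% spec$ar_lags, NA_real_, 0),
    ifelse(seq_len(q) %in% spec$ma_lags, NA_real_, 0),
    if (spec$include_constant) NA_real_,
    rep(NA_real_, ncol(X))
  )
  af <- stats::arima(as.numeric(y), order = c(p, 0L, q),
                     include.mean = spec$include_constant,
                     xreg = X, fixed = fixed, transform.pars = FALSE,
                     method = "CSS-ML")
  est <- stats::coef(af)
  free <- is.na(fixed)
  se <- rep(NA_real_, length(est)); names(se) <- names(est)
  se[free] <- sqrt(pmax(diag(af$var.coef), 0))
  want <- c(if (spec$include_constant) "intercept", colnames(X))
  est_w <- est[want]; se_w <- se[want]
  names(est_w)[names(est_w) == "intercept"] <- "(Intercept)"
  list(estimate = est_w, se = se_w, residuals = as.numeric(stats::residuals(af)),
       sigma = sqrt(af$sigma2), df = NA_integer_)
}

new_intervention_fit <- function(terms, estimate, se, residuals, keys, n,
                                 error_model, whiteness, direction, spec = NULL,
                                 df = NA_integer_) {
  tval <- estimate / se
  pval <- if (!is.na(df)) 2 * stats::pt(-abs(tval), df) else 2 * stats::pnorm(-abs(tval))
  dummy_row <- grep("^dummy$", terms)
  support <- if (length(dummy_row)) {
    est <- estimate[dummy_row]
    (if (direction == "positive") est > 0 else est < 0) &&
      abs(est) > 1.96 * se[dummy_row]
  } else NA
  structure(list(
    coefficients = data.frame(term = terms, estimate = unname(estimate),
                              se = unname(se), t = unname(tval), p = unname(pval),
                              stringsAsFactors = FALSE),
    residuals = residuals, keys = keys, n = n,
    error_model = error_model, whiteness = whiteness,
    direction = direction, support = support, error_spec = spec
  ), class = "intervention_fit")
}

#' Intervention regression of an outcome series on the outlier dummy
#'
#' Regresses an outcome [monthly_series()] (typically the NHW minus NHB male
#' neonatal risk difference) on the 0/1 high-stillbirth indicator. With
#' `error_model = "auto"` the outcome is first checked for autocorrelation
#' with a Ljung-Box test: if it passes (p >= `alpha`), the model is ordinary
#' least squares with classical SEs; otherwise the regression is embedded in
#' the AIC-selected sparse ARMA error structure of the outcome. Support for
#' the working hypothesis is declared when the dummy coefficient exceeds
#' 1.96 x SE in the hypothesized direction; two-sided p-values are reported
#' regardless.
#'
#' @param outcome Outcome [monthly_series()].
#' @param dummy Aligned 0/1 [monthly_series()] with at least one 1 and one 0.
#' @param error_model `"auto"` (default), `"iid"`, or `"arma"`.
#' @param direction Hypothesized sign of the dummy effect, `"positive"`
#'   (default) or `"negative"`.
#' @param lb_lags,alpha Ljung-Box lags and significance level for the
#'   whiteness screen (defaults 12 and 0.05).
#' @param max_lag Candidate-grid depth if an ARMA error structure is needed.
#' @return An object of class `intervention_fit`: `coefficients` (term,
#'   estimate, se, t, p), `residuals`, `n`, `error_model` used, `whiteness`
#'   (the screening test), `support`, and `error_spec` (ARMA error
#'   specification, if any).
#' @examples
#' keys <- cohort_window(1995, 1, 60)
#' d <- monthly_series(rep(c(0, 1), c(55, 5)), keys, "dummy")
#' y <- monthly_series(0.02 + 0.05 * as.numeric(d) + rnorm(60, 0, 0.01), keys, "y")
#' fit_intervention(y, d)
#' @export
fit_intervention <- function(outcome, dummy, error_model = c("auto", "iid", "arma"),
                             direction = c("positive", "negative"),
                             lb_lags = 12L, alpha = 0.05, max_lag = 12L) {
  error_model <- match.arg(error_model)
  direction <- match.arg(direction)
  if (inherits(outcome, "monthly_series") && inherits(dummy, "monthly_series"))
    check_aligned(outcome, dummy)
  y <- as.numeric(outcome)
  x <- as.numeric(dummy)
  n <- length(y)
  if (length(x) != n) stop("outcome and dummy differ in length")
  if (length(unique(x)) < 2L)
    stop("the intervention dummy is constant; the coefficient is not identified")
  if (n <= 3L) stop("too few observations for the intervention regression")
  keys <- if (inherits(outcome, "monthly_series")) cohort_keys(outcome) else NULL

  wt <- whiteness_test(y, lags = min(lb_lags, floor(n / 2) - 1L))
  use <- switch(error_model,
                auto = if (wt$p_value >= alpha) "iid" else "arma",
                error_model)

  if (use == "iid") {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    est <- stats::coef(fit)
    se <- sm$coefficients[, "Std. Error"]
    res <- as.numeric(stats::residuals(fit))
    out <- new_intervention_fit(c("(Intercept)", "dummy"), est, se, res, keys, n,
                                "iid", wt, direction, df = n - 2L)
  } else {
    sel <- select_model(y, candidate_specs(max_lag))
    X <- cbind(dummy = x)
    fr <- fit_arma_regression(y, X, sel$spec)
    out <- new_intervention_fit(c("(Intercept)", "dummy"), fr$estimate, fr$se,
                                fr$residuals, keys, n, "arma", wt, direction,
                                spec = sel$spec)
  }
  out
}

#' @export
print.intervention_fit <- function(x, ...) {
  cat("<intervention_fit> n = ", x$n, ", errors: ", x$error_model,
      if (!is.null(x$error_spec)) paste0(" [", format(x$error_spec), "]"),
      "\n", sep = "")
  tab <- x$coefficients
  tab[, -1L] <- signif(tab[, -1L], 4)
  print(tab, row.names = FALSE)
  cat("  outcome Ljung-Box(", x$whiteness$lags, ") p = ",
      signif(x$whiteness$p_value, 3), "\n", sep = "")
  if (!is.na(x$support))
    cat("  hypothesis (", x$direction, " dummy effect, |t| > 1.96): ",
        if (x$support) "supported" else "not supported", "\n", sep = "")
  invisible(x)
}

#' Male-female robustness model
#'
#' Repeats the intervention regression with the outcome specified as the NHB
#' male minus NHB female neonatal risk difference. Under the selection-in-
#' utero account, the male excess risk should shrink in high-stillbirth
#' cohorts, so the hypothesized dummy effect is negative.
#'
#' @param table A `cohort_table` containing both sexes for NHB.
#' @param result An [detect_high_outliers()] result on the same cohorts.
#' @param ... Passed to [fit_intervention()].
#' @return An `intervention_fit` (attribute `outcome_mean` records the mean
#'   of the outcome series).
#' @export
robustness_male_female <- function(table, result, ...) {
  z3 <- risk_difference(neonatal_risk(table, "NHB", "M"),
                        neonatal_risk(table, "NHB", "F"))
  d <- dummy_series(result, cohort_keys(z3))
  out <- fit_intervention(z3, d, direction = "negative", ...)
  attr(out, "outcome_mean") <- mean(z3)
  attr(out, "outcome_range") <- range(z3)
  out
}

#' Null check with the continuous deviation series
#'
#' Adds the continuous sex-ratio deviation series (residuals net of detected
#' outliers) to the intervention regression, to check that routine
#' fluctuations -- as opposed to flagged extremes -- carry no association
#' with the outcome.
#'
#' @param outcome Outcome [monthly_series()].
#' @param dummy Aligned 0/1 indicator series.
#' @param deviation Aligned continuous deviation series
#'   (see [deviation_series()]).
#' @param error_model,direction,lb_lags,alpha,max_lag As [fit_intervention()].
#' @return An `intervention_fit` with a `deviation` coefficient row.
#' @export
continuous_null_check <- function(outcome, dummy, deviation,
                                  error_model = c("auto", "iid", "arma"),
                                  direction = c("positive", "negative"),
                                  lb_lags = 12L, alpha = 0.05, max_lag = 12L) {
  error_model <- match.arg(error_model)
  direction <- match.arg(direction)
  if (inherits(outcome, "monthly_series")) {
    if (inherits(dummy, "monthly_series")) check_aligned(outcome, dummy)
    if (inherits(deviation, "monthly_series")) check_aligned(outcome, deviation)
  }
  y <- as.numeric(outcome); x <- as.numeric(dummy); z <- as.numeric(deviation)
  n <- length(y)
  if (length(x) != n || length(z) != n) stop("series are not aligned")
  if (length(unique(x)) < 2L) stop("the intervention dummy is constant")
  if (qr(cbind(1, x, z))$rank < 3L)
    stop("deviation series is collinear with the dummy; ",
         "the joint regression is not identified")
  keys <- if (inherits(outcome, "monthly_series")) cohort_keys(outcome) else NULL

  wt <- whiteness_test(y, lags = min(lb_lags, floor(n / 2) - 1L))
  use <- switch(error_model,
                auto = if (wt$p_value >= alpha) "iid" else "arma",
                error_model)
  terms <- c("(Intercept)", "dummy", "deviation")
  if (use == "iid") {
    fit <- stats::lm(y ~ x + z)
    sm <- summary(fit)
    new_intervention_fit(terms, stats::coef(fit),
                         sm$coefficients[, "Std. Error"],
                         as.numeric(stats::residuals(fit)), keys, n,
                         "iid", wt, direction, df = n - 3L)
  } else {
    sel <- select_model(y, candidate_specs(max_lag))
    fr <- fit_arma_regression(y, cbind(dummy = x, deviation = z), sel$spec)
    new_intervention_fit(terms, fr$estimate, fr$se, fr$residuals, keys, n,
                         "arma", wt, direction, spec = sel$spec)
  }
}
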