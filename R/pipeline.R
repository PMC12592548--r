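# End-to-end analysis: cohort table -> sex-ratio model -> outlier flags ->
# intervention regressions -> report.

#' Run the conception-cohort stillbirth analysis on a cohort table
#'
#' Executes the four-step test: (1) AIC-selected sparse ARMA model of the NHB
#' male/female stillbirth sex-ratio series; (2) detection of high-stillbirth
#' outlier cohorts from its residuals; (3--4) intervention regression of the
#' NHW minus NHB male neonatal risk difference on the outlier dummy, with the
#' male-female robustness model and the continuous-deviation null check.
#'
#' @param table A `cohort_table`.
#' @param multiplier Outlier critical value in residual-SD units
#'   (default 2.83).
#' @param outlier_mode `"iterative"` (default; Chang-Tiao-Chen additive
#'   outliers) or `"simple"`.
#' @param sigma_method Residual scale estimator for outlier detection.
#' @param max_lag Candidate-grid depth for model identification (default 12).
#' @param with_robustness,with_continuous Run the secondary models? Default
#'   `TRUE`.
#' @return An object of class `eptb_analysis` bundling the series, the
#'   selected ratio model, the outlier result, and the regression fits.
#' @examples
#' \donttest{
#' sim <- simulate_records(sim_config(), seed = 11)
#' tab <- build_cohort_table(filter_records(sim$records)$records, seed = 12)
#' an <- analyze_cohorts(tab)
#' an$main
#' }
#' @export
analyze_cohorts <- function(table, multiplier = 2.83,
                            outlier_mode = c("iterative", "simple"),
                            sigma_method = c("sd", "mad"),
                            max_lag = 12L,
                            with_robustness = TRUE, with_continuous = TRUE) {
  outlier_mode <- match.arg(outlier_mode)
  sigma_method <- match.arg(sigma_method)

  ratio <- stillbirth_sex_ratio(table, "NHB")
  ratio_fit <- select_model(ratio, candidate_specs(max_lag))
  outliers <- detect_high_outliers(ratio_fit, multiplier = multiplier,
                                   mode = outlier_mode,
                                   sigma_method = sigma_method)
  if (!length(outliers$flagged_idx))
    stop("no high-stillbirth cohorts were flagged at ", multiplier,
         " x sigma; the intervention regression is not identified")
  dummy <- dummy_series(outliers, cohort_keys(ratio))

  z2 <- risk_difference(neonatal_risk(table, "NHW", "M"),
                        neonatal_risk(table, "NHB", "M"))
  main <- fit_intervention(z2, dummy, max_lag = max_lag)

  robustness <- if (with_robustness)
    robustness_male_female(table, outliers, max_lag = max_lag) else NULL
  continuous <- if (with_continuous)
    continuous_null_check(z2, dummy, deviation_series(ratio_fit, outliers),
                          max_lag = max_lag) else NULL

  structure(list(
    summary = cohort_summary(table),
    ratio = ratio,
    ratio_fit = ratio_fit,
    outliers = outliers,
    dummy = dummy,
    outcome = z2,
    main = main,
    robustness = robustness,
    continuous = continuous,
    cohort_seed = attr(table, "seed"),
    multiplier = multiplier,
    outlier_mode = outlier_mode
  ), class = "eptb_analysis")
}

#' @export
print.eptb_analysis <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

fmt_coef_table <- function(fit) {
  tab <- fit$coefficients
  sprintf("    %-12s %10.4f  (SE %.4f, T = %.2f, p = %.4g)",
          tab$term, tab$estimate, tab$se, tab$t, tab$p)
}

#' Human-readable analysis report
#'
#' Renders the full analysis -- summary statistics, the selected sex-ratio
#' model, flagged cohorts, every regression table with per-100 rescalings,
#' and the seeds/configuration used -- as text.
#'
#' @param analysis An [analyze_cohorts()] result.
#' @return Character vector of report lines (one element per line).
#' @export
report <- function(analysis) {
  stopifnot(inherits(analysis, "eptb_analysis"))
  x <- analysis
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))

  add("== Conception-cohort stillbirth selection analysis ==")
  add("")
  add("-- Summary statistics (per conception cohort) --")
  s <- x$summary
  add(sprintf("    %-4s %-3s %-16s %9s %9s %8s %6s %6s",
              "race", "sex", "measure", "total", "mean", "sd", "min", "max"))
  for (i in seq_len(nrow(s)))
    add(sprintf("    %-4s %-3s %-16s %9d %9.2f %8.2f %6d %6d",
                s$race[i], s$sex[i], s$measure[i], s$total[i],
                s$monthly_mean[i], s$monthly_sd[i], s$min[i], s$max[i]))
  add("")
  add("-- Step 1: stillbirth sex-ratio model (lowest AIC) --")
  add("    series mean ", sprintf("%.4f", mean(x$ratio)),
      ", sd ", sprintf("%.4f", stats::sd(x$ratio)))
  add("    selected: ", format(x$ratio_fit$spec),
      "  (AIC ", sprintf("%.2f", x$ratio_fit$aic), ")")
  cf <- x$ratio_fit$coef
  for (nm in names(cf))
    if (is.na(x$ratio_fit$se[nm]) || x$ratio_fit$se[nm] > 0 || cf[nm] != 0)
      add(sprintf("    %-10s %10.4f  (SE %s)", nm, cf[nm],
                  ifelse(is.na(x$ratio_fit$se[nm]), "n/a",
                         sprintf("%.4f", x$ratio_fit$se[nm]))))
  add("    residual sd ", sprintf("%.4f", x$ratio_fit$sigma))
  if (!is.null(x$ratio_fit$lb))
    add("    residual Ljung-Box(", x$ratio_fit$lb$lags, ") p = ",
        sprintf("%.3f", x$ratio_fit$lb$p_value))
  add("")
  add("-- Step 2: high male stillbirth cohorts (", x$outlier_mode,
      " mode, ", x$multiplier, " x sigma) --")
  add("    flagged ", length(x$outliers$flagged_idx), " cohorts: ",
      paste(x$outliers$flagged, collapse = ", "))
  add("")
  add("-- Steps 3-4: NHW - NHB male neonatal risk difference --")
  add("    error model: ", x$main$error_model,
      "  (outcome Ljung-Box p = ", sprintf("%.3f", x$main$whiteness$p_value), ")")
  L <- c(L, fmt_coef_table(x$main))
  co <- x$main$coefficients
  b0 <- co$estimate[co$term == "(Intercept)"]
  b1 <- co$estimate[co$term == "dummy"]
  add(sprintf("    per 100 live births: baseline gap %.2f, flagged-cohort gap %.2f (+%.2f)",
              100 * b0, 100 * (b0 + b1), 100 * b1))
  add("    hypothesis (positive dummy effect): ",
      if (isTRUE(x$main$support)) "supported" else "not supported")
  if (!is.null(x$robustness)) {
    add("")
    add("-- Robustness: NHB male - NHB female risk difference --")
    add(sprintf("    outcome mean %.4f, range [%.4f, %.4f]",
                attr(x$robustness, "outcome_mean"),
                attr(x$robustness, "outcome_range")[1L],
                attr(x$robustness, "outcome_range")[2L]))
    L <- c(L, fmt_coef_table(x$robustness))
    add("    hypothesis (negative dummy effect): ",
        if (isTRUE(x$robustness$support)) "supported" else "not supported")
  }
  if (!is.null(x$continuous)) {
    add("")
    add("-- Null check: continuous deviation covariate --")
    L <- c(L, fmt_coef_table(x$continuous))
  }
  add("")
  add("-- Provenance --")
  add("    cohort randomization seed: ",
      if (is.null(x$cohort_seed)) "n/a" else x$cohort_seed)
  L
}

#' Simulate, cohort, and analyze in one call
#'
#' Convenience wrapper: generates synthetic vital records, filters them,
#' builds the cohort table, and runs [analyze_cohorts()]. All randomness is
#' governed by one top-level seed from which the generator and cohorting
#' seeds are drawn.
#'
#' @param config A [sim_config()].
#' @param seed Top-level integer seed.
#' @param ... Passed to [analyze_cohorts()].
#' @return A list with `sim` (records + ground truth), `table`, `tally`, and
#'   `analysis`, plus the derived `seeds`.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  sim <- simulate_records(config, seed = seeds[1L])
  filt <- filter_records(sim$records)
  tab <- build_cohort_table(filt$records, seed = seeds[2L],
                            start_cohort = config$start_cohort,
                            n_months = config$n_months)
  analysis <- analyze_cohorts(tab, ...)
  list(sim = sim, table = tab, tally = filt$tally, analysis = analysis,
       seeds = c(simulate = seeds[1L], cohort = seeds[2L]))
}
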