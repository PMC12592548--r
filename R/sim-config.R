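#' Configuration for the synthetic vital-records generator
#'
#' Bundles every tunable of the generator with defaults calibrated to the
#' published monthly summary statistics of US extremely preterm (20--27
#' completed weeks) NH Black and NH white singleton births, 288 monthly
#' conception cohorts (Jan 1995 -- Dec 2018). The stillbirth sex-ratio process
#' is a sparse-lag ARMA (AR at lag 3, MA at lag 9) whose level and innovation
#' scale are solved, on the log scale, so that the stationary ratio series has
#' the target mean and SD (defaults 1.214 and 0.1476).
#'
#' Monthly expected counts additionally carry a shared smooth latent
#' log-intensity (AR(1), `intensity_ar`) that reproduces the over-Poisson
#' monthly dispersion of real counts (secular trend plus seasonality); its
#' coefficients of variation are derived from the published monthly SDs via
#' var = mean + mean^2 * cv^2.
#'
#' @param n_months Number of monthly conception cohorts (default 288).
#' @param start_cohort `c(year, month)` of the first cohort (default Jan 1995).
#' @param target_ratio_mean,target_ratio_sd Targets for the stationary mean
#'   and SD of the simulated sex-ratio series; used to solve `mean_log_ratio`
#'   and `innovation_sd` when those are `NULL`.
#' @param mean_log_ratio Level of the ratio process on the modeling scale
#'   (log scale unless `ratio_scale = "raw"`); `NULL` = solve from targets.
#' @param ar_lag,ar_coef Sparse autoregressive term (defaults lag 3, 0.148).
#' @param ma_lag,ma_coef Sparse moving-average term (defaults lag 9, 0.161).
#' @param innovation_sd Innovation SD of the ratio process; `NULL` = solve
#'   from targets.
#' @param ratio_scale `"log"` (default; dynamics on log ratio, exponentiated,
#'   keeps ratios positive) or `"raw"` (dynamics on the ratio itself, as the
#'   published model is written).
#' @param outlier_months Integer cohort indices receiving a planted
#'   high-stillbirth bump (default none). [study_outlier_months()] gives the
#'   seven indices whose calendar months match the flagged cohorts of the
#'   motivating analysis.
#' @param outlier_bump Amount added to the (log-)ratio in outlier months
#'   (default 0.6, about 3.5 residual SDs of the observed count ratio --
#'   unambiguous under a 2.83 SD criterion).
#' @param base_counts Named per-group mean monthly counts
#'   (`nhb_m_lb`, `nhb_f_lb`, `nhw_m_lb`, `nhw_f_lb`, `nhb_m_sb`, `nhb_f_sb`).
#'   The NHB male stillbirth mean is implied by ratio x female mean; the
#'   `nhb_m_sb` entry is retained for reference and validation only.
#' @param base_neonatal_risk Named per-group baseline neonatal death risks
#'   (`nhb_m`, `nhb_f`, `nhw_m`, `nhw_f`), each in (0,1).
#' @param delta Absolute reduction of the NHB male neonatal risk in outlier
#'   months (default 0.044).
#' @param ga_distribution Probability weights over completed gestational weeks
#'   20--27 (default declining).
#' @param lb_dispersion_cv,sb_dispersion_cv CV of the latent count intensity
#'   for live births and stillbirths.
#' @param intensity_ar AR(1) coefficient of the latent log-intensity.
#' @param seed Default seed used by the simulators when none is passed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$innovation_sd
#' @export
sim_config <- function(n_months = 288L,
                       start_cohort = c(1995L, 1L),
                       target_ratio_mean = 1.214,
                       target_ratio_sd = 0.1476,
                       mean_log_ratio = NULL,
                       ar_lag = 3L, ar_coef = 0.148,
                       ma_lag = 9L, ma_coef = 0.161,
                       innovation_sd = NULL,
                       ratio_scale = c("log", "raw"),
                       outlier_months = integer(0),
                       outlier_bump = 0.6,
                       base_counts = c(nhb_m_lb = 344, nhb_f_lb = 318,
                                       nhw_m_lb = 366, nhw_f_lb = 314,
                                       nhb_m_sb = 167, nhb_f_sb = 139),
                       base_neonatal_risk = c(nhb_m = 0.3232, nhb_f = 0.2869,
                                              nhw_m = 0.3418, nhw_f = 0.3145),
                       delta = 0.044,
                       ga_distribution = c(0.22, 0.18, 0.15, 0.13,
                                           0.11, 0.08, 0.07, 0.06),
                       lb_dispersion_cv = 0.083,
                       sb_dispersion_cv = 0.066,
                       intensity_ar = 0.95,
                       seed = 1L) {
  ratio_scale <- match.arg(ratio_scale)
  n_months <- as.integer(n_months)
  if (n_months < 1L) stop("n_months must be positive")
  if (abs(ar_coef) >= 1) stop("non-stationary configuration: |ar_coef| must be < 1, got ", ar_coef)
  if (abs(ma_coef) >= 1) stop("non-invertible configuration: |ma_coef| must be < 1, got ", ma_coef)
  if (ar_lag < 1L || ma_lag < 1L) stop("ar_lag and ma_lag must be positive integers")

  # stationary variance multiplier of the ARMA filter: 1 + sum(psi_j^2)
  g <- arma_variance_factor(ar_lag, ar_coef, ma_lag, ma_coef)
  if (ratio_scale == "log") {
    s2 <- log(1 + (target_ratio_sd / target_ratio_mean)^2)
    if (is.null(mean_log_ratio)) mean_log_ratio <- log(target_ratio_mean) - s2 / 2
    if (is.null(innovation_sd)) innovation_sd <- sqrt(s2 / g)
  } else {
    if (is.null(mean_log_ratio)) mean_log_ratio <- target_ratio_mean
    if (is.null(innovation_sd)) innovation_sd <- target_ratio_sd / sqrt(g)
  }
  if (innovation_sd < 0) stop("innovation_sd must be non-negative")

  required_counts <- c("nhb_m_lb", "nhb_f_lb", "nhw_m_lb", "nhw_f_lb",
                       "nhb_m_sb", "nhb_f_sb")
  if (!all(required_counts %in% names(base_counts)))
    stop("base_counts must name: ", paste(required_counts, collapse = ", "))
  if (any(base_counts <= 0)) stop("all base_counts must be > 0")
  required_risks <- c("nhb_m", "nhb_f", "nhw_m", "nhw_f")
  if (!all(required_risks %in% names(base_neonatal_risk)))
    stop("base_neonatal_risk must name: ", paste(required_risks, collapse = ", "))
  if (any(base_neonatal_risk <= 0 | base_neonatal_risk >= 1))
    stop("all baseline risks must lie in (0, 1)")
  if (delta < 0 || delta >= base_neonatal_risk[["nhb_m"]])
    stop("delta must be in [0, base_neonatal_risk['nhb_m'])")
  outlier_months <- as.integer(outlier_months)
  if (length(outlier_months) && (any(outlier_months < 1L) || any(outlier_months > n_months)))
    stop("outlier_months must be cohort indices in 1..n_months")
  if (anyDuplicated(outlier_months)) stop("outlier_months must be unique")
  if (length(ga_distribution) != 8L || any(ga_distribution < 0) || sum(ga_distribution) <= 0)
    stop("ga_distribution must be 8 non-negative weights (weeks 20..27)")
  if (abs(intensity_ar) >= 1) stop("|intensity_ar| must be < 1")
  if (lb_dispersion_cv < 0 || sb_dispersion_cv < 0) stop("dispersion CVs must be >= 0")

  structure(list(
    n_months = n_months,
    start_cohort = as.integer(start_cohort),
    target_ratio_mean = target_ratio_mean,
    target_ratio_sd = target_ratio_sd,
    mean_log_ratio = mean_log_ratio,
    ar_lag = as.integer(ar_lag), ar_coef = ar_coef,
    ma_lag = as.integer(ma_lag), ma_coef = ma_coef,
    innovation_sd = innovation_sd,
    ratio_scale = ratio_scale,
    outlier_months = outlier_months,
    outlier_bump = outlier_bump,
    base_counts = base_counts,
    base_neonatal_risk = base_neonatal_risk,
    delta = delta,
    ga_distribution = ga_distribution / sum(ga_distribution),
    lb_dispersion_cv = lb_dispersion_cv,
    sb_dispersion_cv = sb_dispersion_cv,
    intensity_ar = intensity_ar,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Cohort indices of the seven flagged study months
#'
#' The seven conception cohorts flagged in the motivating analysis
#' (Jan-1999, May-2000, Jul-2000, Jul-2001, Aug-2007, Jul-2008, Oct-2012) as
#' indices into the 288-month window starting Jan 1995. Convenient as
#' `outlier_months` for study-conditions simulations.
#'
#' @return Integer vector of length 7.
#' @examples
#' study_outlier_months()
#' @export
study_outlier_months <- function() c(49L, 65L, 67L, 79L, 152L, 163L, 214L)

# 1 + sum(psi^2) for the sparse ARMA filter (1 + theta B^q) / (1 - phi B^p)
arma_variance_factor <- function(ar_lag, ar_coef, ma_lag, ma_coef, lag_max = 500L) {
  ar <- if (ar_coef != 0) c(rep(0, ar_lag - 1L), ar_coef) else numeric(0)
  ma <- if (ma_coef != 0) c(rep(0, ma_lag - 1L), ma_coef) else numeric(0)
  if (!length(ar) && !length(ma)) return(1)
  psi <- stats::ARMAtoMA(ar = ar, ma = ma, lag.max = lag_max)
  1 + sum(psi^2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_months, " cohorts from ",
      cohort_key(x$start_cohort[1L], x$start_cohort[2L]), "\n", sep = "")
  cat("  ratio process (", x$ratio_scale, " scale): level ",
      signif(x$mean_log_ratio, 4), ", AR lag ", x$ar_lag, " = ", x$ar_coef,
      ", MA lag ", x$ma_lag, " = ", x$ma_coef,
      ", innovation sd ", signif(x$innovation_sd, 4), "\n", sep = "")
  cat("  planted outliers: ", length(x$outlier_months),
      " months, bump ", x$outlier_bump, ", delta ", x$delta, "\n", sep = "")
  invisible(x)
}
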