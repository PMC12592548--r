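# Analytic monthly series and summary statistics derived from a cohort table.

# pull one group's column as an index-ordered vector, with cohort keys
table_column <- function(table, race, sex, column) {
  sel <- table$race == race & table$sex == sex
  sub <- table[sel, , drop = FALSE]
  sub <- sub[order(sub$index), , drop = FALSE]
  list(values = sub[[column]], keys = sub$cohort)
}

#' Monthly stillbirth sex ratio
#'
#' Male divided by female stillbirth counts per conception cohort for one
#' race group. Positive spikes in this series index excess male loss in
#' utero.
#'
#' @param table A `cohort_table`.
#' @param race `"NHB"` (default) or `"NHW"`.
#' @return A [monthly_series()] of ratios.
#' @examples
#' sim <- simulate_records(sim_config(n_months = 12), seed = 1)
#' tab <- build_cohort_table(sim$records, seed = 2, n_months = 12)
#' stillbirth_sex_ratio(tab)
#' @export
stillbirth_sex_ratio <- function(table, race = "NHB") {
  m <- table_column(table, race, "M", "stillbirths")
  f <- table_column(table, race, "F", "stillbirths")
  zero <- f$values == 0
  if (any(zero))
    stop("zero female stillbirth count in cohort(s) ",
         paste(utils::head(f$keys[zero], 5L), collapse = ", "),
         "; the sex ratio is undefined")
  monthly_series(m$values / f$values, m$keys,
                 paste0(race, " male/female stillbirth ratio"))
}

#' Monthly neonatal death risk
#'
#' Neonatal deaths (death before 28 days among live births) divided by live
#' births, per conception cohort, for one race x sex group.
#'
#' @param table A `cohort_table`.
#' @param race `"NHB"` or `"NHW"`.
#' @param sex `"M"` or `"F"`.
#' @return A [monthly_series()] with values in `[0, 1]`.
#' @export
neonatal_risk <- function(table, race, sex) {
  lb <- table_column(table, race, sex, "livebirths")
  nd <- table_column(table, race, sex, "neonatal_deaths")
  zero <- lb$values == 0
  if (any(zero))
    stop("zero live births for ", race, " ", sex, " in cohort(s) ",
         paste(utils::head(lb$keys[zero], 5L), collapse = ", "))
  monthly_series(nd$values / lb$values, lb$keys,
                 paste0(race, " ", sex, " neonatal death risk"))
}

#' Risk difference between two aligned monthly series
#'
#' @param a,b Aligned [monthly_series()]; the result is `a - b` cohort by
#'   cohort.
#' @return A [monthly_series()] of differences.
#' @export
risk_difference <- function(a, b) {
  check_aligned(a, b)
  monthly_series(as.numeric(a) - as.numeric(b), cohort_keys(a),
                 paste0(attr(a, "label"), " minus ", attr(b, "label")))
}

#' Summary statistics of a cohort table
#'
#' One row per race x sex x measure with the total count, monthly mean,
#' monthly SD, and range across cohorts, in the layout of a standard
#' summary-statistics table. All-zero measures (e.g. stillbirths for a group
#' the table does not cover) are dropped.
#'
#' @param table A `cohort_table`.
#' @return data.frame with columns `race`, `sex`, `measure`, `total`,
#'   `monthly_mean`, `monthly_sd`, `min`, `max`.
#' @examples
#' sim <- simulate_records(sim_config(n_months = 12), seed = 1)
#' tab <- build_cohort_table(sim$records, seed = 2, n_months = 12)
#' cohort_summary(tab)
#' @export
cohort_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty cohort table")
  measures <- c(livebirths = "live births", neonatal_deaths = "neonatal deaths",
                stillbirths = "stillbirths")
  rows <- list()
  for (race in c("NHB", "NHW")) for (sex in c("M", "F")) {
    for (mi in seq_along(measures)) {
      col <- names(measures)[mi]
      v <- table_column(table, race, sex, col)$values
      if (!length(v) || all(v == 0)) next
      rows[[length(rows) + 1L]] <- data.frame(
        race = race, sex = sex, measure = measures[[mi]],
        total = sum(v), monthly_mean = mean(v),
        monthly_sd = if (length(v) > 1L) stats::sd(v) else 0,
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
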