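#' Monthly conception-cohort series
#'
#' A thin wrapper around a numeric vector: one value per conception cohort,
#' keyed by `"YYYY-MM"` cohort strings, with a label describing what the
#' values are. All analytic series (stillbirth sex ratio, neonatal risks,
#' risk differences, 0/1 intervention dummies, residuals) use this container.
#'
#' @param values Numeric vector, one value per cohort; no missing values.
#' @param keys Character vector of `"YYYY-MM"` cohort keys, same length,
#'   strictly consecutive calendar months.
#' @param label Short description of the series.
#' @return An object of class `monthly_series` (numeric with `keys` and
#'   `label` attributes).
#' @examples
#' monthly_series(rnorm(12), cohort_window(1995, 1, 12), "example")
#' @export
monthly_series <- function(values, keys, label = "") {
  values <- as.numeric(values)
  keys <- as.character(keys)
  if (length(values) != length(keys))
    stop("values and keys differ in length (", length(values), " vs ", length(keys), ")")
  if (anyNA(values)) stop("monthly series '", label, "' contains missing values")
  km <- parse_cohort_key(keys)
  idx <- month_index(km$year, km$month)
  if (length(idx) > 1L && any(diff(idx) != 1L))
    stop("cohort keys must be consecutive calendar months")
  structure(values, keys = keys, label = label, class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  k <- cohort_keys(x)
  cat("<monthly_series> ", attr(x, "label"), "\n",
      "  ", length(x), " cohorts: ", k[1L], " .. ", k[length(k)], "\n", sep = "")
  cat("  mean ", signif(mean(x), 4), ", sd ", signif(stats::sd(x), 4),
      ", range [", signif(min(x), 4), ", ", signif(max(x), 4), "]\n", sep = "")
  invisible(x)
}

#' Cohort keys of a monthly series
#' @param x A `monthly_series`.
#' @return Character vector of `"YYYY-MM"` keys.
#' @export
cohort_keys <- function(x) attr(x, "keys")

#' @export
`[.monthly_series` <- function(x, i, ...) {
  monthly_series(unclass(x)[i], cohort_keys(x)[i], attr(x, "label"))
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(cohort = cohort_keys(x), value = as.numeric(x))
}

# error unless two series share an identical cohort window
check_aligned <- function(a, b) {
  if (!identical(cohort_keys(a), cohort_keys(b)))
    stop("series are not aligned on the same cohort window: '",
         attr(a, "label"), "' vs '", attr(b, "label"), "'")
  invisible(TRUE)
}

#' Write a monthly series as two-column delimited text
#'
#' @param x A `monthly_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
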