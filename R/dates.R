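# Integer calendar arithmetic on months and days.
#
# All conception-cohort bookkeeping reduces to two maps: (year, month) -> the
# serial day number of the first of that month, and a serial day -> the month
# containing it. Both are precomputed over a generous span so that per-record
# work is pure vectorized integer arithmetic.

# wide span so long simulated series (thousands of months) stay in range
.CAL_YEARS <- 1950:2450

# serial day (days since 1970-01-01) of the first day of each month in
# .CAL_YEARS, plus the month labels; built once at load time
.month_table <- local({
  years <- rep(.CAL_YEARS, each = 12L)
  months <- rep(1:12, times = length(.CAL_YEARS))
  start <- as.integer(as.Date(sprintf("%04d-%02d-01", years, months)))
  list(year = years, month = months, start = start)
})

#' Number of days in a calendar month
#'
#' Respects leap Februaries.
#'
#' @param year,month Integer vectors (recycled).
#' @return Integer vector of month lengths (28--31).
#' @examples
#' days_in_month(2000, 2) # 29
#' days_in_month(1995, 2) # 28
#' @export
days_in_month <- function(year, month) {
  i <- month_index(year, month)
  ends <- c(diff(.month_table$start), 31L)
  ends[i]
}

# position of (year, month) in the calendar table; errors on out-of-table input
month_index <- function(year, month) {
  if (any(month < 1L | month > 12L)) stop("month must be in 1..12")
  i <- (year - .CAL_YEARS[1L]) * 12L + month
  if (any(year < .CAL_YEARS[1L]) || any(year > .CAL_YEARS[length(.CAL_YEARS)]))
    stop("year outside supported calendar range ",
         .CAL_YEARS[1L], "-", .CAL_YEARS[length(.CAL_YEARS)])
  as.integer(i)
}

# serial day of (year, month, day)
serial_day <- function(year, month, day) {
  .month_table$start[month_index(year, month)] + as.integer(day) - 1L
}

# serial day -> list(year, month) of the containing month
month_of_day <- function(serial) {
  i <- findInterval(serial, .month_table$start)
  if (any(i < 1L)) stop("serial day before supported calendar range")
  list(year = .month_table$year[i], month = .month_table$month[i])
}

#' Format a cohort key
#'
#' Cohort keys are `"YYYY-MM"` strings naming an estimated conception month.
#'
#' @param year,month Integer vectors.
#' @return Character vector of keys.
#' @export
cohort_key <- function(year, month) sprintf("%04d-%02d", year, month)

# "YYYY-MM" -> list(year, month)
parse_cohort_key <- function(key) {
  y <- as.integer(substr(key, 1L, 4L))
  m <- as.integer(substr(key, 6L, 7L))
  if (any(is.na(y)) || any(is.na(m))) stop("malformed cohort key: ", key[is.na(y) | is.na(m)][1L])
  list(year = y, month = m)
}

#' Consecutive cohort keys
#'
#' The ordered `"YYYY-MM"` keys of `n_months` consecutive conception cohorts.
#'
#' @param start_year,start_month First cohort.
#' @param n_months Number of cohorts.
#' @return Character vector of keys.
#' @examples
#' cohort_window(1995, 1, 3)
#' @export
cohort_window <- function(start_year, start_month, n_months) {
  i0 <- month_index(start_year, start_month)
  idx <- i0 + seq_len(n_months) - 1L
  cohort_key(.month_table$year[idx], .month_table$month[idx])
}
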