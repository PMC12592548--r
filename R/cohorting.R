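# Conception-cohort construction from individual vital-event records:
# schema-checked reading, analytic-population filtering with an exact
# exclusion tally, randomized event-day conception-month assignment, and
# aggregation to a per-cohort count table.

RECORD_COLUMNS <- c("event_type", "event_year", "event_month",
                    "gestational_weeks", "sex", "race_eth", "plurality",
                    "neonatal_death")

#' Read vital-event records from delimited text
#'
#' Expects the fixed comma-separated schema with header
#' `event_type,event_year,event_month,gestational_weeks,sex,race_eth,plurality,neonatal_death`;
#' empty fields encode missing values. Rows that fail to parse (non-numeric
#' years/months/weeks, unknown event types) are reported with their line
#' numbers.
#'
#' @param path Path to the records file.
#' @return data.frame of vital records.
#' @export
read_vital_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event_type = "character",
                                       sex = "character",
                                       race_eth = "character"),
                        na.strings = "")
  if (!identical(sort(names(df)), sort(RECORD_COLUMNS)))
    stop("records file must have columns: ", paste(RECORD_COLUMNS, collapse = ","))
  df <- df[RECORD_COLUMNS]
  bad <- which(!(df$event_type %in% c("stillbirth", "livebirth")) |
                 is.na(df$event_year) | is.na(df$event_month) |
                 df$event_month < 1 | df$event_month > 12)
  if (length(bad))
    stop("unparseable record rows (file lines, counting the header): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  df$neonatal_death <- as.logical(df$neonatal_death)
  df
}

#' Filter records to the analytic population
#'
#' Retains singleton NH Black / NH white records with known gestational age in
#' 20--27 completed weeks. Each dropped record is tallied under the first rule
#' it violates, in the order: missing gestational age, missing plurality,
#' non-singleton, race/ethnicity other or missing, gestational age outside
#' 20--27 weeks. Retained records missing sex are a hard error: the analytic
#' population is defined as reporting sex on every record.
#'
#' @param records data.frame of vital records.
#' @return A list with `records` (retained rows) and `tally`, a named integer
#'   vector of exclusion counts satisfying
#'   `nrow(input) == nrow(retained) + sum(tally)` exactly.
#' @examples
#' sim <- simulate_records(sim_config(n_months = 6), seed = 1)
#' filt <- filter_records(sim$records)
#' filt$tally
#' @export
filter_records <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(cond, lab) ifelse(is.na(reason) & cond, lab, reason)
  reason <- mark(is.na(records$gestational_weeks), "missing_ga")
  reason <- mark(is.na(records$plurality), "missing_plurality")
  reason <- mark(records$plurality != 1L, "non_singleton")
  reason <- mark(is.na(records$race_eth) | !(records$race_eth %in% c("NHB", "NHW")),
                 "race_other_or_missing")
  reason <- mark(records$gestational_weeks < 20L | records$gestational_weeks > 27L,
                 "ga_outside_20_27")
  keep <- is.na(reason)
  if (any(keep & is.na(records$sex)))
    stop("retained analytic records with missing sex: ",
         sum(keep & is.na(records$sex)),
         " (the analytic population reports sex on every record)")
  tally <- c(missing_ga = 0L, missing_plurality = 0L, non_singleton = 0L,
             race_other_or_missing = 0L, ga_outside_20_27 = 0L)
  tab <- table(reason[!keep])
  tally[names(tab)] <- as.integer(tab)
  stopifnot(n == sum(keep) + sum(tally))
  list(records = records[keep, , drop = FALSE], tally = tally)
}

#' Back-calculate a conception month from a full event date
#'
#' Deterministic core of the conception-month estimate: conception date =
#' event date minus 7 x completed gestational weeks (days), reduced to its
#' calendar month. Leap years are respected.
#'
#' @param year,month,day Event date components (vectors, recycled).
#' @param ga_weeks Completed gestational weeks at the event.
#' @return A list with `year` and `month` vectors of the conception month.
#' @examples
#' conception_from_event(2000, 7, 15, 20) # Feb 2000
#' @export
conception_from_event <- function(year, month, day, ga_weeks) {
  if (any(is.na(ga_weeks))) stop("gestational age must be present")
  month_of_day(serial_day(year, month, day) - 7L * as.integer(ga_weeks))
}

#' Assign estimated conception months by event-day randomization
#'
#' The source records carry only the event year and month. Each record is
#' given a pseudo event day drawn uniformly over the true length of its event
#' month (29 days in leap Februaries); the conception date is that pseudo date
#' minus 7 x gestational weeks in days, and the estimated cohort is the
#' calendar month containing it.
#'
#' @param records data.frame of (filtered) vital records.
#' @param seed Optional integer seed; the draw consumes the R RNG stream.
#' @return Character vector of `"YYYY-MM"` cohort keys, one per record.
#' @examples
#' sim <- simulate_records(sim_config(n_months = 6), seed = 1)
#' head(assign_conception_month(sim$records, seed = 2))
#' @export
assign_conception_month <- function(records, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(records$gestational_weeks))) stop("gestational age must be present")
  len <- days_in_month(records$event_year, records$event_month)
  day <- 1L + as.integer(floor(stats::runif(nrow(records)) * len))
  conc <- conception_from_event(records$event_year, records$event_month, day,
                                records$gestational_weeks)
  cohort_key(conc$year, conc$month)
}

#' Aggregate records into a conception-cohort count table
#'
#' Runs one conception-month randomization under `seed` and counts
#' stillbirths, live births, and neonatal deaths per cohort x race x sex cell
#' over the retained cohort window. Records whose estimated conception falls
#' outside the window are tallied (attribute `out_of_window`), never silently
#' dropped.
#'
#' @param records Filtered vital records (see [filter_records()]).
#' @param seed Integer seed for the event-day randomization; recorded on the
#'   result.
#' @param start_cohort `c(year, month)` of the first retained cohort.
#' @param n_months Number of retained cohorts (default 288).
#' @return A data.frame of class `cohort_table` with columns `cohort`,
#'   `index`, `race`, `sex`, `stillbirths`, `livebirths`, `neonatal_deaths`
#'   (one row per cohort x race x sex), and attributes `seed`,
#'   `out_of_window`, `n_months`.
#' @examples
#' sim <- simulate_records(sim_config(n_months = 6), seed = 1)
#' tab <- build_cohort_table(sim$records, seed = 2,
#'                           start_cohort = c(1995, 1), n_months = 6)
#' head(tab)
#' @export
build_cohort_table <- function(records, seed, start_cohort = c(1995L, 1L),
                               n_months = 288L) {
  if (nrow(records) == 0L) stop("cohort aggregation received no records")
  keys <- cohort_window(start_cohort[1L], start_cohort[2L], n_months)
  ck <- assign_conception_month(records, seed = seed)
  idx <- match(ck, keys)
  in_win <- !is.na(idx)

  race <- factor(records$race_eth, levels = c("NHB", "NHW"))
  sex <- factor(records$sex, levels = c("M", "F"))
  gid <- (as.integer(race) - 1L) * 2L + as.integer(sex)  # NHB-M, NHB-F, NHW-M, NHW-F
  cell <- (idx - 1L) * 4L + gid
  ncell <- n_months * 4L

  is_sb <- records$event_type == "stillbirth"
  is_lb <- records$event_type == "livebirth"
  is_nd <- is_lb & !is.na(records$neonatal_death) & records$neonatal_death
  sb <- tabulate(cell[in_win & is_sb], nbins = ncell)
  lb <- tabulate(cell[in_win & is_lb], nbins = ncell)
  nd <- tabulate(cell[in_win & is_nd], nbins = ncell)

  grid_gid <- rep(1:4, times = n_months)
  ord <- order(rep(seq_len(n_months), each = 4L))  # already ordered; kept explicit
  tab <- data.frame(
    cohort = rep(keys, each = 4L),
    index = rep(seq_len(n_months), each = 4L),
    race = c("NHB", "NHB", "NHW", "NHW")[grid_gid],
    sex = c("M", "F", "M", "F")[grid_gid],
    stillbirths = sb[ord],
    livebirths = lb[ord],
    neonatal_deaths = nd[ord],
    stringsAsFactors = FALSE
  )
  structure(tab,
            seed = seed,
            out_of_window = sum(!in_win),
            n_months = as.integer(n_months),
            start_cohort = as.integer(start_cohort),
            class = c("cohort_table", "data.frame"))
}

#' Stability of the conception-month randomization
#'
#' Repeats the event-day randomization `n_runs` times on a fixed record set
#' and correlates, between every pair of runs, the per-cohort total record
#' counts. High correlations indicate that the randomized day assignment does
#' not materially perturb cohort composition.
#'
#' @param records Filtered vital records.
#' @param n_runs Number of randomization runs (>= 2).
#' @param seeds Optional integer vector of per-run seeds (length `n_runs`).
#' @param start_cohort,n_months Cohort window (as [build_cohort_table()]).
#' @return An `n_runs x n_runs` Pearson correlation matrix with attribute
#'   `min` (the minimum off-diagonal correlation).
#' @export
randomization_stability <- function(records, n_runs = 100L, seeds = NULL,
                                    start_cohort = c(1995L, 1L),
                                    n_months = 288L) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  if (is.null(seeds)) seeds <- sample.int(.Machine$integer.max, n_runs)
  if (length(seeds) != n_runs) stop("seeds must have length n_runs")
  keys <- cohort_window(start_cohort[1L], start_cohort[2L], n_months)
  counts <- matrix(0L, n_months, n_runs)
  for (r in seq_len(n_runs)) {
    ck <- assign_conception_month(records, seed = seeds[r])
    idx <- match(ck, keys)
    counts[, r] <- tabulate(idx[!is.na(idx)], nbins = n_months)
  }
  sds <- apply(counts, 2L, stats::sd)
  if (any(is.na(sds) | sds == 0))
    stop("a randomization run produced a constant cohort-count series; ",
         "correlation is undefined")
  cm <- stats::cor(counts)
  attr(cm, "min") <- min(cm[lower.tri(cm)])
  attr(cm, "seeds") <- seeds
  cm
}

#' Write a cohort table with its JSON metadata sidecar
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path; metadata (randomization seed, out-of-window
#'   tally, window) is written to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = attr(table, "seed"),
               out_of_window = attr(table, "out_of_window"),
               n_months = attr(table, "n_months"),
               start_cohort = attr(table, "start_cohort"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path CSV path.
#' @return A `cohort_table` (metadata restored from the sidecar if present).
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort", "index", "race", "sex", "stillbirths", "livebirths",
            "neonatal_deaths")
  if (!all(need %in% names(tab)))
    stop("cohort table must have columns: ", paste(need, collapse = ","))
  meta_path <- paste0(path, ".meta.json")
  n_months <- max(tab$index)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(tab,
            seed = meta$seed,
            out_of_window = meta$out_of_window,
            n_months = as.integer(if (!is.null(meta$n_months)) meta$n_months else n_months),
            start_cohort = as.integer(unlist(meta$start_cohort %||% parse_cohort_key(tab$cohort[1L]))),
            class = c("cohort_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
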