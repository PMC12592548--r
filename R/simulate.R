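#' Simulate the monthly stillbirth sex-ratio process
#'
#' Generates one realization of the sparse-lag ARMA recursion
#' `w_t = phi * w_{t-p} + a_t + theta * a_{t-q}` on the configured scale
#' (log by default), adds the planted outlier bump in outlier months, and
#' returns the ratio series. A burn-in of at least ten times the maximum lag
#' is generated and discarded so the series is effectively stationary.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A [monthly_series()] of simulated male/female stillbirth ratios.
#' @examples
#' r <- simulate_ratio_process(sim_config(), seed = 42)
#' mean(r)
#' @export
simulate_ratio_process <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  z <- ratio_process_values(config)
  keys <- cohort_window(config$start_cohort[1L], config$start_cohort[2L], config$n_months)
  monthly_series(z, keys, "NHB male/female stillbirth ratio (simulated)")
}

# raw numeric ratio values; consumes RNG
ratio_process_values <- function(config) {
  n <- config$n_months
  burn <- max(10L * max(config$ar_lag, config$ma_lag), 120L)
  N <- n + burn
  a <- stats::rnorm(N, 0, config$innovation_sd)
  x <- a
  if (config$ma_coef != 0) {
    q <- config$ma_lag
    x <- a + config$ma_coef * c(rep(0, q), a[seq_len(N - q)])
  }
  if (config$ar_coef != 0) {
    filt <- c(rep(0, config$ar_lag - 1L), config$ar_coef)
    x <- as.numeric(stats::filter(x, filt, method = "recursive"))
  }
  z <- config$mean_log_ratio + x[(burn + 1L):N]
  if (length(config$outlier_months))
    z[config$outlier_months] <- z[config$outlier_months] + config$outlier_bump
  if (config$ratio_scale == "log") exp(z) else z
}

#' Simulate individual-level vital-event records with known ground truth
#'
#' For each conception month and group, draws stillbirth and live-birth counts
#' from a Poisson family floored at 1 (aggregation in the motivating design
#' guarantees non-zero cells). Expected live-birth counts carry a shared
#' smooth latent intensity reproducing realistic over-Poisson monthly
#' dispersion; the NHB male stillbirth mean is the simulated sex-ratio process
#' times the (intensity-adjusted) female mean, so the realized count ratio is
#' centred on the latent ratio. Neonatal deaths are independent Bernoulli per
#' live birth at the group risk, with the NHB male risk reduced by `delta` in
#' planted outlier months. Each record receives a conception day uniform in
#' its cohort month, a gestational age from `ga_distribution`, and an event
#' date equal to conception date + 7 x (completed weeks) days, reduced to
#' event year/month.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A list of class `sim_vitals` with elements
#'   \describe{
#'     \item{records}{data.frame of vital records in the standard schema
#'       (`event_type`, `event_year`, `event_month`, `gestational_weeks`,
#'       `sex`, `race_eth`, `plurality`, `neonatal_death`).}
#'     \item{truth}{ground truth: `counts` (realized per-cohort, per-group
#'       stillbirth/livebirth/neonatal-death counts), `outlier_months`
#'       (indices), `outlier_keys`, `delta`, `ratio` (latent series).}
#'   }
#' @examples
#' sim <- simulate_records(sim_config(n_months = 12), seed = 7)
#' nrow(sim$records)
#' @export
simulate_records <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_months
  keys <- cohort_window(config$start_cohort[1L], config$start_cohort[2L], n)

  ratio <- ratio_process_values(config)
  if (config$ratio_scale == "raw" && any(ratio <= 0))
    stop("raw-scale ratio process produced non-positive ratios; ",
         "reduce innovation_sd or use ratio_scale = 'log'")

  # shared smooth latent intensity, unit marginal SD
  rho <- config$intensity_ar
  u <- as.numeric(stats::filter(stats::rnorm(n + 200L, 0, sqrt(1 - rho^2)),
                                rho, method = "recursive"))[201L:(n + 200L)]
  fac_lb <- exp(config$lb_dispersion_cv * u - config$lb_dispersion_cv^2 / 2)
  fac_sb <- exp(config$sb_dispersion_cv * u - config$sb_dispersion_cv^2 / 2)

  bc <- config$base_counts
  lambda <- list(
    nhb_f_sb = bc[["nhb_f_sb"]] * fac_sb,
    nhb_m_sb = ratio * bc[["nhb_f_sb"]] * fac_sb,
    nhb_m_lb = bc[["nhb_m_lb"]] * fac_lb,
    nhb_f_lb = bc[["nhb_f_lb"]] * fac_lb,
    nhw_m_lb = bc[["nhw_m_lb"]] * fac_lb,
    nhw_f_lb = bc[["nhw_f_lb"]] * fac_lb
  )
  if (any(vapply(lambda, function(l) any(l <= 0), logical(1L))))
    stop("configuration implies a zero or negative expected count")
  counts <- lapply(lambda, function(l) pmax(stats::rpois(n, l), 1L))

  # per-group monthly neonatal risks
  risk <- list(
    nhb_m = rep(config$base_neonatal_risk[["nhb_m"]], n),
    nhb_f = rep(config$base_neonatal_risk[["nhb_f"]], n),
    nhw_m = rep(config$base_neonatal_risk[["nhw_m"]], n),
    nhw_f = rep(config$base_neonatal_risk[["nhw_f"]], n)
  )
  if (length(config$outlier_months))
    risk$nhb_m[config$outlier_months] <- risk$nhb_m[config$outlier_months] - config$delta

  groups <- list(
    list(id = "nhb_m_sb", race = "NHB", sex = "M", type = "stillbirth", risk = NULL),
    list(id = "nhb_f_sb", race = "NHB", sex = "F", type = "stillbirth", risk = NULL),
    list(id = "nhb_m_lb", race = "NHB", sex = "M", type = "livebirth", risk = risk$nhb_m),
    list(id = "nhb_f_lb", race = "NHB", sex = "F", type = "livebirth", risk = risk$nhb_f),
    list(id = "nhw_m_lb", race = "NHW", sex = "M", type = "livebirth", risk = risk$nhw_m),
    list(id = "nhw_f_lb", race = "NHW", sex = "F", type = "livebirth", risk = risk$nhw_f)
  )

  km <- parse_cohort_key(keys)
  cstart <- serial_day(km$year, km$month, 1L)  # per-cohort month start
  clen <- days_in_month(km$year, km$month)
  ga_levels <- 20:27

  rec_list <- vector("list", length(groups))
  nd_counts <- matrix(0L, n, 4L,
                      dimnames = list(NULL, c("nhb_m", "nhb_f", "nhw_m", "nhw_f")))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    cm <- counts[[g$id]]
    total <- sum(cm)
    midx <- rep.int(seq_len(n), cm)
    day <- 1L + as.integer(floor(stats::runif(total) * clen[midx]))
    ga <- sample(ga_levels, total, replace = TRUE, prob = config$ga_distribution)
    ev <- month_of_day(cstart[midx] + (day - 1L) + 7L * ga)
    nd <- rep(NA, total)
    if (g$type == "livebirth") {
      nd <- stats::runif(total) < g$risk[midx]
      rk <- paste0(tolower(g$race), "_", tolower(g$sex))
      nd_counts[, rk] <- tabulate(midx[nd], nbins = n)
    }
    rec_list[[gi]] <- data.frame(
      event_type = g$type,
      event_year = ev$year,
      event_month = ev$month,
      gestational_weeks = ga,
      sex = g$sex,
      race_eth = g$race,
      plurality = 1L,
      neonatal_death = nd,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  truth_counts <- data.frame(
    cohort = rep(keys, times = 4L),
    index = rep(seq_len(n), times = 4L),
    race = rep(c("NHB", "NHB", "NHW", "NHW"), each = n),
    sex = rep(c("M", "F", "M", "F"), each = n),
    stillbirths = c(counts$nhb_m_sb, counts$nhb_f_sb, integer(n), integer(n)),
    livebirths = c(counts$nhb_m_lb, counts$nhb_f_lb, counts$nhw_m_lb, counts$nhw_f_lb),
    neonatal_deaths = c(nd_counts[, "nhb_m"], nd_counts[, "nhb_f"],
                        nd_counts[, "nhw_m"], nd_counts[, "nhw_f"]),
    stringsAsFactors = FALSE
  )

  structure(list(
    records = records,
    truth = list(
      counts = truth_counts,
      outlier_months = config$outlier_months,
      outlier_keys = keys[config$outlier_months],
      delta = config$delta,
      ratio = monthly_series(ratio, keys, "latent stillbirth sex ratio")
    )
  ), class = "sim_vitals")
}

#' Write simulated vital records as delimited text
#'
#' Emits the fixed-schema CSV consumed by [read_vital_records()]; missing
#' values are written as empty fields.
#'
#' @param records data.frame of vital records (e.g. `simulate_records()$records`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vital_records <- function(records, path) {
  out <- records
  out$neonatal_death <- ifelse(is.na(out$neonatal_death), "",
                               as.integer(out$neonatal_death))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of a [simulate_records()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    outlier_months = truth$outlier_months,
    outlier_keys = truth$outlier_keys,
    delta = truth$delta,
    counts = truth$counts
  )
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
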