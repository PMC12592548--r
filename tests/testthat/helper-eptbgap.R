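# Shared fixture builders. Everything is generated in code; no stored data.

# a clean vital record row, with overridable fields
make_record <- function(event_type = "livebirth", event_year = 1995L,
                        event_month = 6L, gestational_weeks = 24L,
                        sex = "M", race_eth = "NHB", plurality = 1L,
                        neonatal_death = FALSE) {
  data.frame(event_type = event_type, event_year = event_year,
             event_month = event_month, gestational_weeks = gestational_weeks,
             sex = sex, race_eth = race_eth, plurality = plurality,
             neonatal_death = neonatal_death, stringsAsFactors = FALSE)
}

# a cohort table with constant per-month counts for every group
make_table <- function(n_months = 12L, sb_m = 10L, sb_f = 10L,
                       lb = 100L, nd = 30L, start = c(1995L, 1L)) {
  keys <- cohort_window(start[1L], start[2L], n_months)
  grid <- expand.grid(gi = 1:4, index = seq_len(n_months))
  tab <- data.frame(
    cohort = keys[grid$index],
    index = grid$index,
    race = c("NHB", "NHB", "NHW", "NHW")[grid$gi],
    sex = c("M", "F", "M", "F")[grid$gi],
    stillbirths = rep(c(sb_m, sb_f, 0L, 0L), n_months),
    livebirths = rep(lb, 4L * n_months),
    neonatal_deaths = rep(nd, 4L * n_months),
    stringsAsFactors = FALSE
  )
  structure(tab, n_months = as.integer(n_months), seed = NA_integer_,
            start_cohort = as.integer(start), out_of_window = 0L,
            class = c("cohort_table", "data.frame"))
}

# overwrite one group's count column with explicit per-month values
set_group <- function(table, race, sex, column, values) {
  sel <- which(table$race == race & table$sex == sex)
  sel <- sel[order(table$index[sel])]
  stopifnot(length(sel) == length(values))
  table[sel, column] <- values
  table
}

# small reduced-scale generator config for fast multi-replicate tests
small_config <- function(n_months = 72L, scale = 0.25, ...) {
  sim_config(n_months = n_months,
             base_counts = c(nhb_m_lb = 344, nhb_f_lb = 318, nhw_m_lb = 366,
                             nhw_f_lb = 314, nhb_m_sb = 167, nhb_f_sb = 139) * scale,
             ...)
}
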