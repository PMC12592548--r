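# Conception-cohort construction: filtering, back-calculation, aggregation.

test_that("conception month back-calculation matches calendar arithmetic", {
  # frozen against independent date arithmetic: as.Date("2000-07-15") - 140
  # is 2000-02-26 (leap February), as.Date("1996-03-03") - 189 is 1995-08-27
  c1 <- conception_from_event(2000, 7, 15, 20)
  expect_equal(c(c1$year, c1$month), c(2000, 2))
  c2 <- conception_from_event(1996, 3, 3, 27)
  expect_equal(c(c2$year, c2$month), c(1995, 8))
  # degenerate GA = 0: conception month equals event month
  c3 <- conception_from_event(2005, 11, 14, 0)
  expect_equal(c(c3$year, c3$month), c(2005, 11))
  expect_error(conception_from_event(2000, 7, 15, NA), "gestational age")
})

test_that("month lengths respect leap years", {
  expect_equal(days_in_month(2000, 2), 29L)
  expect_equal(days_in_month(2100, 2), 28L)  # century non-leap
  expect_equal(days_in_month(c(1995, 1996), 2), c(28L, 29L))
  expect_equal(days_in_month(1995, c(1, 4, 12)), c(31L, 30L, 31L))
})

test_that("pseudo event days stay within the true month length", {
  recs <- do.call(rbind, replicate(200, make_record(event_year = 1996L,
                                                    event_month = 2L,
                                                    gestational_weeks = 20L),
                                   simplify = FALSE))
  keys <- assign_conception_month(recs, seed = 1)
  # 1996-02 events, GA 140 days: conception in Sep or Oct 1995 only
  expect_true(all(keys %in% c("1995-09", "1995-10")))
  # both months actually occur across 200 uniform draws
  expect_setequal(unique(keys), c("1995-09", "1995-10"))
})

test_that("filtering applies the analytic-population rules with exact tally", {
  recs <- rbind(
    make_record(),                                   # retained
    make_record(sex = "F"),                          # retained
    make_record(race_eth = "NHW"),                   # retained
    make_record(event_type = "stillbirth",
                neonatal_death = NA),                # retained
    make_record(gestational_weeks = NA),             # missing GA
    make_record(plurality = NA),                     # missing plurality
    make_record(plurality = 2L),                     # non-singleton
    make_record(race_eth = "hispanic"),              # race other
    make_record(race_eth = NA),                      # race missing
    make_record(gestational_weeks = 28L),            # GA out of window (high)
    make_record(gestational_weeks = 19L)             # GA out of window (low)
  )
  filt <- filter_records(recs)
  expect_equal(nrow(filt$records), 4L)
  expect_equal(sum(filt$tally), 7L)
  expect_equal(unname(filt$tally["non_singleton"]), 1L)
  expect_equal(unname(filt$tally["race_other_or_missing"]), 2L)
  expect_equal(unname(filt$tally["ga_outside_20_27"]), 2L)
  expect_equal(nrow(recs), nrow(filt$records) + sum(filt$tally))
  # boundary weeks 20 and 27 are inside the window
  keep <- filter_records(rbind(make_record(gestational_weeks = 20L),
                               make_record(gestational_weeks = 27L)))
  expect_equal(nrow(keep$records), 2L)
})

test_that("each dropped record is tallied under the first violated rule", {
  r <- make_record(gestational_weeks = NA, plurality = 2L, race_eth = "other")
  filt <- filter_records(r)
  expect_equal(unname(filt$tally["missing_ga"]), 1L)
  expect_equal(sum(filt$tally), 1L)
})

test_that("retained records with missing sex are a hard error", {
  expect_error(filter_records(make_record(sex = NA)), "missing sex")
  # missing sex on an otherwise-excluded record is fine
  filt <- filter_records(make_record(sex = NA, plurality = 2L))
  expect_equal(nrow(filt$records), 0L)
})

test_that("a single record lands in exactly one cell with count one", {
  r <- make_record(event_type = "stillbirth", event_year = 1995L,
                   event_month = 6L, gestational_weeks = 20L,
                   neonatal_death = NA)
  tab <- build_cohort_table(r, seed = 3, n_months = 12L)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 48L)
  expect_equal(sum(tab$stillbirths), 1L)
  expect_equal(sum(tab$livebirths), 0L)
  hit <- tab[tab$stillbirths == 1L, ]
  expect_equal(hit$race, "NHB")
  expect_equal(hit$sex, "M")
  # 1995-06 event minus 140 days: conception Jan or Feb 1995
  expect_true(hit$cohort %in% c("1995-01", "1995-02"))
})

test_that("aggregation conserves records and is seed-deterministic", {
  sim <- simulate_records(small_config(n_months = 24L), seed = 5)
  filt <- filter_records(sim$records)
  t1 <- build_cohort_table(filt$records, seed = 9, n_months = 24L)
  t2 <- build_cohort_table(filt$records, seed = 9, n_months = 24L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "seed"), 9)
  total_cells <- sum(t1$stillbirths) + sum(t1$livebirths)
  expect_equal(total_cells + attr(t1, "out_of_window"), nrow(filt$records))
  expect_true(all(t1$neonatal_deaths <= t1$livebirths))
  expect_error(build_cohort_table(filt$records[0, ], seed = 1),
               "no records")
})

test_that("rebuilt cohort counts track ground truth up to boundary reassignment", {
  # Re-randomizing the event day moves roughly a third of records into a
  # neighbouring cohort, so per-group correlations with the generator truth
  # sit near 0.8-0.9, not 1 (bound fixed by a Monte-Carlo oracle run at the
  # full 288-cohort window, where the slow intensity component is expressed).
  sim <- simulate_records(sim_config(), seed = 31)
  tab <- build_cohort_table(sim$records, seed = 32)
  tr <- sim$truth$counts
  for (race in c("NHB", "NHW")) for (sex in c("M", "F")) {
    a <- tr[tr$race == race & tr$sex == sex, ]
    a <- a[order(a$index), ]
    b <- tab[tab$race == race & tab$sex == sex, ]
    b <- b[order(b$index), ]
    expect_gt(cor(a$livebirths, b$livebirths), 0.7)
    if (race == "NHB") expect_gt(cor(a$stillbirths, b$stillbirths), 0.7)
  }
})

test_that("randomization stability behaves at the edges", {
  sim <- simulate_records(small_config(n_months = 12L), seed = 6)
  # identical seeds give correlation exactly 1
  cm <- randomization_stability(sim$records, n_runs = 3L, seeds = c(4L, 4L, 4L),
                                n_months = 12L)
  expect_equal(max(abs(cm - 1)), 0)
  # a handful of records still yields finite correlations
  few <- sim$records[1:10, ]
  cm2 <- randomization_stability(few, n_runs = 4L, seeds = 11:14,
                                 n_months = 12L)
  expect_true(all(is.finite(cm2)))
  expect_true(all(abs(cm2) <= 1))
  # a degenerate one-cohort window has no variance to correlate
  expect_error(randomization_stability(few, n_runs = 2L, seeds = 1:2,
                                       n_months = 1L),
               "constant")
  expect_error(randomization_stability(sim$records, n_runs = 1L), "at least 2")
})

test_that("records survive a write/read round trip", {
  sim <- simulate_records(small_config(n_months = 6L), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vital_records(sim$records, path)
  back <- read_vital_records(path)
  expect_equal(back$event_year, sim$records$event_year)
  expect_equal(back$neonatal_death, sim$records$neonatal_death)
  expect_equal(back$race_eth, sim$records$race_eth)
})
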