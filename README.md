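# eptbgap

Conception-cohort time-series tests of whether unusually high male
stillbirth loss widens the non-Hispanic white minus non-Hispanic Black gap
in neonatal survival among extremely preterm (ePTB; 20–27 completed weeks)
male singletons.

## The problem

In the US, NH Black infants born extremely preterm show a *lower* risk of
neonatal death than NH white infants at the same gestational ages. One
explanation is selection in utero (left truncation): conception cohorts
that lose more fetuses to stillbirth leave behind a hardier live-born
subset. `eptbgap` implements, as a tested pipeline, the conception-cohort
test of that account for analysts of vital-statistics records:

1. estimate each record's conception month from its event month and
   gestational age (`event date − 7 × GA` days, with a randomized
   within-month pseudo day);
2. build the monthly NHB male/female stillbirth sex ratio
   `Z1_t = M_t / F_t` and model it as a sparse-lag ARMA with constant,
   identified by minimum AIC (e.g. `Z1_t = c + (1 + θB⁹)/(1 − φB³) a_t`);
3. flag "high male stillbirth" cohorts whose residual exceeds the 99.5%
   band (2.83 × residual SD, high side), by direct thresholding or by the
   iterative Chang–Tiao–Chen additive-outlier routine;
4. regress the neonatal risk difference
   `Z2_t = risk(NHW male)_t − risk(NHB male)_t` on the 0/1 flagged-cohort
   indicator, `Z2_t = β0 + β1 X_t + a_t` (OLS when `Z2` passes a Ljung–Box
   whiteness screen, ARMA-embedded errors otherwise), declaring support
   when `β1 > 1.96 · SE`; plus a male–female robustness model
   (`Z3_t = risk(NHB M) − risk(NHB F)`, hypothesized negative effect) and
   a continuous-residual null check.

Because the real 1995–2019 US fetal death and cohort linked birth/infant
death files are restricted, the package ships a synthetic vital-records
generator (`simulate_records()`) calibrated to the published monthly count
magnitudes, with known planted outlier months and a planted risk reduction
`delta` for parameter-recovery testing.

## Worked example

```r
library(eptbgap)

cfg <- sim_config(outlier_months = study_outlier_months())  # 7 planted cohorts
res <- run_pipeline(cfg, seed = 101)
print(res$analysis)
```

Abridged output (one ~475,000-record synthetic replicate at study scale):

```
-- Step 1: stillbirth sex-ratio model (lowest AIC) --
    series mean 1.2340, sd 0.1961
    selected: c + AR{1} + MA{6}  (AIC -137.85)
    residual sd 0.1878
    residual Ljung-Box(12) p = 0.873

-- Step 2: high male stillbirth cohorts (iterative mode, 2.83 x sigma) --
    flagged 6 cohorts: 2000-05, 2007-08, 2008-07, 2009-11, 2012-08, 2012-10

-- Steps 3-4: NHW - NHB male neonatal risk difference --
    error model: iid  (outcome Ljung-Box p = 0.256)
    (Intercept)      0.0160  (SE 0.0020, T = 7.91, p = 5.571e-14)
    dummy            0.0295  (SE 0.0140, T = 2.10, p = 0.03686)
    per 100 live births: baseline gap 1.60, flagged-cohort gap 4.55 (+2.95)
    hypothesis (positive dummy effect): supported
```

Reading it: the baseline survival gap is 1.6 excess NH white male neonatal
deaths per 100 ePTB live births; in flagged high-stillbirth cohorts the gap
widens by 2.95 per 100 (4 of the 6 flags are planted months; the planted
effect was 4.4 per 100 — point interventions are attenuated ~2/3 by the
randomized conception-day assignment, see the methods vignette). The
robustness model recovers the mirrored negative effect on the NHB
male-female gap, and the continuous-deviation covariate is null, as the
selection account predicts.

A thin CLI wraps the same functions:

```sh
inst/cli/eptbgap simulate --seed 1 --records records.csv
inst/cli/eptbgap cohort   --records records.csv --seed 2 --table cohorts.csv
inst/cli/eptbgap analyze  --table cohorts.csv
inst/cli/eptbgap run-all  --seed 1 --out-dir results/
```

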