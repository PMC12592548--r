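Package: eptbgap
Title: Stillbirth Selection and the Race-Specific Neonatal Survival Gap in
    Extremely Preterm Conception Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether months of unusually high male
    stillbirth loss in a conception cohort widen the non-Hispanic white minus
    non-Hispanic Black gap in neonatal survival among extremely preterm (20-27
    completed weeks) male singletons. Implements conception-cohort construction
    from individual vital-event records via randomized event-day assignment,
    monthly stillbirth sex-ratio and neonatal-risk series, Box-Jenkins
    identification of sparse-lag ARMA models with AIC selection, simple and
    iterative (Chang-Tiao-Chen) additive-outlier detection, and intervention
    (dummy-variable) regression of the risk-difference series with classical
    inference. A synthetic vital-records generator with known ground truth
    stands in for the restricted-access US vital statistics files and supports
    parameter-recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
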