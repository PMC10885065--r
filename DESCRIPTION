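Package: stepcap
Title: Submaximal Step-Test Assessment of Cardiovascular Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for individualized submaximal step testing of
    cardiovascular capacity in adults. Scores the IPAQ short form into weekly
    MET-minutes and a three-level physical-activity classification,
    individualizes the step-test protocol (step height from a ponderation of
    sex, age class, fitness, BMI and smoking status; progressive cadence
    schedule; termination at a fraction of age-predicted maximal heart rate),
    reduces heart-rate/oxygen-uptake time series to resting, stage-end and
    recovery summaries, estimates VO2max by extrapolating the individual
    HR-VO2 regression to age-predicted HRmax, evaluates and refits (backward
    stepwise) a VO2max prediction equation based on one-minute heart-rate
    recovery (HRR60), classifies cardiovascular capacity from HRR60, and runs
    a measured-versus-predicted agreement battery (paired t, Cohen's d,
    two-way mixed absolute-agreement ICC, Bland-Altman). A synthetic-cohort
    simulator with known ground truth exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
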