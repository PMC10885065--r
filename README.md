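# stepcap

Submaximal step-test assessment of cardiovascular capacity in R.

Maximal oxygen uptake (VO₂max) is the benchmark measure of
cardiorespiratory fitness, but a true maximal test is impractical or
inadvisable for much of the general population. `stepcap` implements an
individualized submaximal step-test workflow for exercise physiologists,
sports scientists and health practitioners:

- **IPAQ short-form scoring** — weekly MET-minutes and the Low/Moderate/High
  physical-activity level (`ipaq_score()`).
- **Protocol individualization** — step height from a ponderation of sex,
  age class, fitness, BMI band and smoking status
  (`step_height(cm) = 4 × sum + 15`, range 15–40 cm); progressive cadence
  schedule (15 → 37.5 cycles/min in 2.5 steps); termination when heart rate
  reaches 80% of the Tanaka age-predicted maximum, HRmax = 208 − 0.7·age
  (`step_height()`, `cadence_schedule()`, `target_hr()`,
  `termination_check()`).
- **VO₂max estimation** — reduce a phase-labelled (time, HR, VO₂) series to
  resting, stage-end and recovery summaries, fit the individual HR–VO₂
  regression, and extrapolate it to HRmax (`analyze_session()`,
  `fit_hr_vo2()`, `estimate_vo2max()`); one-minute heart-rate recovery
  HRR₆₀ (`recovery_summary()`).
- **Prediction and classification** — the published equation

  VO₂max = 17.105 + 0.260·HRR₆₀ + 8.563·sex + 4.097·PA_level

  (sex: women 0, men 1; R² = 74.0%, SEE = 4.78), backward stepwise refits
  on new cohorts, and the Poor/Moderate/Good/Excellent rating of
  cardiovascular capacity from HRR₆₀ (`predict_vo2max()`,
  `backward_stepwise()`, `classify_cvc()`).
- **Agreement validation** — paired t, Cohen's d with descriptors, two-way
  mixed absolute-agreement ICC, and Bland–Altman limits of agreement with
  the ≥ 80% coverage criterion (`validate_agreement()`), plus
  summary-level helpers for checking printed tables
  (`paired_t_from_ci()`, `cohens_d_from_summary()`).
- **Synthetic cohorts** — a generator with known ground truth emulating the
  study population, for end-to-end testing without raw data
  (`sim_config()`, `sample_cohort()`, `simulate_session()`,
  `run_validation_study()`).

Results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods (Bland–Altman and HR–VO₂ plots).

## Worked example

Individualize the protocol for a 22-year-old moderately active nonsmoking
man (BMI 23.5):

```r
library(stepcap)
library(tibble)

step_height(tibble(sex = "man", age = 22, pa_level = 2, bmi = 23.5, smoker = FALSE))
#> # A tibble: 1 × 7
#>   sex     age pa_level   bmi smoker ponderation_sum step_height_cm
#>   <chr> <dbl>    <dbl> <dbl> <lgl>            <dbl>          <dbl>
#> 1 man      22        2  23.5 FALSE              3.5             29

target_hr(22)
#> [1] 154.08
```

He steps on a 29 cm platform until his heart rate reaches 154 bpm.
Analyzing a (here simulated) test session:

```r
cfg  <- sim_config(n = 1)
p    <- sample_cohort(cfg, seed = 42)
sess <- simulate_session(p, cfg, seed = 43)
analyze_session(sess, age = p$age)
#>   hr_rest vo2_rest n_points slope intercept    r2  hr_max vo2max  hr_end  hr_60  hrr60
#> 1  68.997    4.015        9 0.352   -20.345 0.998 189.357 46.322 152.037 124.234 27.802
```

The HR–VO₂ line (R² = 0.998 across rest + 8 stage points) extrapolated to
the age-predicted HRmax of 189 bpm gives a measured VO₂max of
46.3 mL·kg⁻¹·min⁻¹. His heart rate fell 27.8 bpm in the first recovery
minute, so the equation predicts

```r
predict_vo2max(tibble(hrr60 = 27.8, sex = "man", pa_level = 2))$vo2max_pred
#> [1] 45.187
classify_cvc(tibble(hrr60 = 27.8))$cvc_class
#> [1] Moderate
```

— a "Moderate" cardiovascular capacity (HRR₆₀ in [25, 40) bpm). A full
synthetic validation study (derive the equation on 30 participants,
validate on 39):

```r
run_validation_study(sim_config(n = 69), seed = 7)$agreement
#> Agreement report (n = 39 pairs)
#>   paired t: mean diff -0.310 (95% CI -2.710 to 2.091), t = -0.261, df = 38, p = 0.795
#>   Cohen's d (pooled_sd): 0.041 [trivial]
#>   ICC(A,1): 0.516 [moderate]
#>   Bland-Altman: bias -0.310, LoA -14.821 to 14.202, 92.3% within (pass)
```

The mean measured-vs-predicted difference is indistinguishable from zero
with a trivial effect size, and 92% of pairs fall inside the limits of
agreement, passing the 80% criterion.

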