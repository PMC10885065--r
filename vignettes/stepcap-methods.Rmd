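---
title: "Submaximal step testing of cardiovascular capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Submaximal step testing of cardiovascular capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcap)
library(dplyr)
```

## The problem

Maximal oxygen uptake (VO~2max~, mL·kg^−1^·min^−1^) is the standard summary
of cardiorespiratory capacity, but measuring it directly requires a maximal
test to exhaustion — inadvisable for much of the general population.
`stepcap` implements a submaximal alternative built around an individualized
step test: the participant steps up and down a platform at a metronome-paced
cadence that increases every minute, and the test stops when heart rate
reaches 80% of the age-predicted maximum. Two quantities carry the
assessment:

* **VO~2max~ by extrapolation.** Heart rate and VO~2~ rise together almost
  linearly across submaximal intensities. An ordinary least-squares line
  fitted to the resting point and three or more stage-end points is
  evaluated at the age-predicted maximal heart rate
  (HR~max~ = 208 − 0.7·age, the Tanaka formula) to estimate VO~2max~.
* **Heart-rate recovery (HRR~60~).** The drop in heart rate over the first
  minute after exercise stops indexes parasympathetic reactivation and
  predicts cardiovascular risk. It drives both a prediction equation for
  VO~2max~ and a four-class qualitative rating of cardiovascular capacity.

The prediction equation, for settings where gas analysis is unavailable, is

$$\widehat{VO}_{2max} = 17.105 + 0.260\,HRR_{60} + 8.563\,\text{sex} +
4.097\,PA_{level},$$

with sex coded 0 for women and 1 for men, and PA~level~ the three-level
IPAQ short-form physical-activity classification treated as a numeric 1/2/3
covariate (the equation carries a single coefficient for it, not dummies).
Its reported fit on the derivation cohort is R² = 74.0% with a standard
error of the estimate (SEE) of 4.78 mL·kg^−1^·min^−1^.

## Protocol individualization

Step height adapts the test to the participant. Five factors are scored —
sex (woman 0.5, man 1), age class (senior 0, adult 0.5, young 1), fitness
class (insufficiently 0 / moderately 0.5 / vigorously active 1), BMI band
(< 25 → 0.5, 25–30 → 0, ≥ 30 → −0.5) and smoking (smoker 0, nonsmoker 0.5)
— and the height is `4 × sum + 15` cm, clamped to [15, 40] cm and rounded
to whole centimetres. Enumerating all 108 categorical profiles shows the
printed factors reach at most 31 cm; the 40 cm ceiling is retained as a
clamp because taller platforms are standard in other protocols, but it is
unreachable by this formula. Fitter profiles step higher so that everyone
reaches the heart-rate target inside the ten-minute cap.

Cadence starts at 15 cycles/min (0.25 Hz) and rises 2.5 cycles/min per
stage to at most 37.5 cycles/min. The stage length is not part of the
published protocol text; one-minute stages are adopted (and configurable)
because ten cadence steps inside a ten-minute cap imply them, and they
match the last-5-s averaging windows. Age-class cut-offs for the
ponderation (young < 35, adult 35–64, senior ≥ 65) are likewise a
documented, configurable default, as is the convenience mapping from IPAQ
level to fitness class (1 → insufficiently, 2 → moderately,
3 → vigorously active), which a directly assessed fitness class overrides.

## Session reduction

Three averaging windows reduce a phase-labelled (time, HR, VO~2~) series:

* resting values: arithmetic means over the final 60 s of rest;
* stage endpoints: means over the last 5 s of each stage;
* recovery: `hr_60` is the mean over the [55 s, 60 s] window of the first
  recovery minute, measured from the end of exercise, and
  `hrr60 = hr_end − hr_60`.

All windows are closed intervals; a sample falling exactly on a boundary
belongs to the earlier window. Samples are averaged arithmetically without
time weighting (a warning fires when fewer than three samples land in a
5-s window), which is exact for regular sampling and a documented
approximation otherwise. `hr_end` defaults to the last-5-s average of the
final stage — consistent with how every other quantity is averaged — with
the instantaneous last pre-recovery sample available by option. VO~2~ may
be absent during recovery; recovery uses heart rate only. Negative
recoveries are flagged, never silently dropped.

The HR–VO~2~ regression requires at least four points (rest plus three
stages). The resting point is included by default, per the protocol's
definition; `include_rest = FALSE` excludes it. A zero-variance heart-rate
design or fewer than four points raises a typed error rather than
returning a degenerate line.

## Refitting and classification

`backward_stepwise()` starts from the full OLS model on the candidate set
{sex, body mass, height, BMI, PA~level~, HRR~60~} (age optionally added)
and repeatedly drops the predictor with the largest p ≥ α (default 0.05),
stopping when all retained predictors are significant. SEE is the residual
standard error with the `n − p − 1` denominator. Exact collinearity is
reported as a degenerate-design error naming the aliased columns.

HRR~60~ classifies cardiovascular capacity as Poor [0, 25), Moderate
[25, 40), Good [40, 55) and Excellent [55, ∞) bpm. The published table
prints Good as 40–54 while the accompanying text says "40 to 55"; the
half-open bands adopted here make the four classes a partition of the
non-negative line and agree with "≥ 55 excellent" in both places. The
sex-specific VO~2max~ reference intervals attached to those classes
(including the McArdle normative columns) ship verbatim as literature
values for reporting; they contain printed gaps, so classification never
keys on them.

## Agreement battery

`validate_agreement()` bundles the measured-vs-predicted validation:

* paired t with 95% CI (df = n − 1, two-sided);
* Cohen's d with descriptors trivial (< 0.20), small (0.20–0.59), moderate
  (0.6–1.19), large (1.2–1.99), very large (≥ 2.0). The default
  denominator is the pooled SD `sqrt((s_m² + s_p²)/2)`: applied to the
  published summary table it reproduces the printed effect size, whereas
  the difference-SD variant gives a slightly larger value; both are
  exposed;
* ICC(A,1): single-measure, two-way mixed, absolute agreement, computed
  from the two-way ANOVA mean squares
  `(MSR − MSE) / (MSR + MSE + (2/n)(MSC − MSE))`, with bands poor (< 0.5),
  moderate, good, excellent (≥ 0.90);
* Bland–Altman: bias ± 1.96·SD of differences, with the criterion that at
  least 80% of pairs fall within the limits. Differences exactly on a
  limit count as within — a deterministic tie rule that matches the
  criterion's "at least" phrasing.

`paired_t_from_ci()` and `cohens_d_from_summary()` recompute these
statistics from printed summary rows (mean difference, CI, group SDs), so
published tables can be checked without raw data.

## The synthetic cohort

Because the original raw data are not redistributable, every pipeline
claim is exercised on synthetic cohorts with known ground truth.
`sim_config()` defaults encode the study conditions: 69 participants
(27 women, 42 men); per-sex age, mass and height moments matching the
reported cohort; per-sex PA-level frequencies matching the reported
distribution (women 15/8/4 across levels 1–3, men 3/24/15); HRR~60~
truncated-normal with mean 37, SD 11, bounds 19–63 bpm (the observed
range); and true VO~2max~ generated from the prediction equation's mean
structure plus Gaussian noise with SD 4.78 — the published SEE. Resting
heart rate and VO~2~ use per-sex means pooled from the reported groups
(women 81/3.4, men 68/3.7, SDs 11/0.7), smoking prevalence 10% (not
reported; a plausible young-adult figure, configurable).

Session kinetics are simulator plumbing, chosen for transparency rather
than physiological fidelity:

* stage steady-state heart rate rises linearly with stage index and is
  calibrated so the crossing stage (drawn uniformly from stages 5–10)
  lands exactly on the 80%·HR~max~ target — mirroring the protocol fact
  that every participant terminated by the heart-rate criterion;
* per-sample VO~2~ lies on the line through (hr~rest~, vo2~rest~) and
  (HR~max~, true VO~2max~), so a noise-free session is recovered *exactly*
  by the estimation pipeline — the key identifiability property tested to
  1 × 10⁻⁶;
* recovery is mono-exponential toward resting heart rate, the simplest
  model consistent with parasympathetic reactivation, with the time
  constant back-solved (by `uniroot`, tolerance 1 × 10⁻¹⁰) so the realized
  last-5-s-window HRR~60~ equals the participant's true HRR~60~; the
  per-participant HRR~60~ ceiling is additionally capped at 90% of the
  termination-to-rest gap so that back-solve always has a root;
* within-stage heart rate steps instantaneously to its steady state (the
  last-5-s windows only ever read steady states); sampling is 1 Hz;
  measurement noise defaults to 2 bpm and 1.0 mL·kg^−1^·min^−1^ per
  sample, which lands individual-fit R² in the 0.97–0.99 band reported
  for real sessions.

What the simulator deliberately does not emulate: correlation between
physical activity, sex and HRR~60~ (covariates are sampled independently
within sex), VO~2~ on-kinetics and slow component, breath-by-breath noise
spectra, and ectopic beats. One visible consequence is that the synthetic
between-subject VO~2max~ spread is smaller than in the real cohort, so
synthetic agreement ICCs run lower than the published one; passing tests
demonstrate the pipeline's correctness and calibration under the stated
generative model, not field performance on real participants.

## IPAQ scoring choices

Weekly MET-minutes use the official short-form weights (walking 3.3,
moderate 4.0, vigorous 8.0), exposed as configuration. The High criterion
"three days of vigorous activity with 1500 MET-min/week" reads the 1500 as
*total* weekly MET-minutes (the official-protocol reading); the seven-day
High clause counts any combination of categories, with a stricter
all-three-categories switch. The "5+ days of at least 30 min" Moderate
clause counts days from every category reporting ≥ 30 min/day, vigorous
included. No minute truncation is applied by default; the official 180
min/day cleaning cap is available as an option. Classification is
monotone: adding activity never lowers the level.

## Problem sizes and numerical conventions

The test suite exercises: enumeration of all 108 categorical step-height
profiles; property checks of the OLS fit, paired t and ICC against
independent brute-force oracles (explicit normal equations and summation
formulas, plus `aov`'s decomposition) on hundreds of random small
instances; 100 noise-free simulated sessions for exact pipeline recovery;
and 100 refits on cohorts of n = 2000 for coefficient recovery, where
backward elimination retains the three generating predictors in every run
and drops all null anthropometric candidates in a fraction of runs
consistent with the α = 0.05 screening level, with 2-SE coverage of each
coefficient at its nominal frequency. Cohort-moment checks use n = 8000.
These sizes keep the default suite under a minute while leaving Monte
Carlo margins well away from their thresholds.

Ties and degeneracies are resolved deterministically throughout: boundary
samples to the earlier window, band boundaries to the upper class
(half-open intervals), differences on a Bland–Altman limit counted within,
zero-variance paired differences reported as t = 0 or ±∞ with a
degeneracy flag rather than an error.

## Limitations

The method targets young adults; the age-predicted HR~max~ formula and the
HRR~60~ cut-offs are not validated here outside that population. VO~2max~
and HR~max~ are both estimated, not measured. The simulator's independence
assumptions understate real covariate structure (see above), so
field-realistic agreement statistics should be obtained from real paired
data via `validate_agreement()`, not from the simulator.
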