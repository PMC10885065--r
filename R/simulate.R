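# Synthetic cohorts and test sessions with known ground truth. The
# generator emulates the study population (young-adult cohort moments and
# per-sex physical-activity frequencies) and the measurement structure of a
# session (rest, progressive stages terminating at 80% of age-predicted
# HRmax, mono-exponential recovery), so the whole pipeline can be exercised
# against simulated truth.

rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  if (any(sd < 0)) stop_validation("sd must be non-negative")
  if (all(sd == 0)) return(rep(mean, length.out = n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a cohort of 69 young adults
#' (27 women, 42 men) with per-sex anthropometric moments, per-sex
#' physical-activity level frequencies, HRR60 distributed truncated-normal
#' (mean 37, SD 11, range 19--63 bpm), and true VO2max generated from the
#' published prediction equation plus Gaussian noise with SD equal to the
#' equation's standard error of the estimate (4.78 mL·kg⁻¹·min⁻¹). Session
#' kinetics (stage steady states, mono-exponential recovery) are simulator
#' plumbing, not study claims.
#'
#' @param n Cohort size.
#' @param prop_men Proportion of men.
#' @param age_mean,age_sd,age_range Age parameters per sex
#'   (named `woman`/`man` where applicable).
#' @param mass_mean,mass_sd Body mass (kg) per sex.
#' @param height_mean,height_sd Height (m) per sex.
#' @param pa_probs Per-sex probabilities over PA levels 1--3 (list with
#'   `woman`, `man`, each summing to 1).
#' @param smoker_prob Probability of being a smoker.
#' @param hr_rest_mean,hr_rest_sd,hr_rest_range Resting heart rate (bpm)
#'   per sex.
#' @param vo2_rest_mean,vo2_rest_sd Resting VO2 (mL·kg⁻¹·min⁻¹) per sex.
#' @param hrr60_mean,hrr60_sd,hrr60_range True HRR60 distribution (bpm).
#' @param outcome_noise_sd SD of the noise on true VO2max about the
#'   equation's mean structure.
#' @param hr_noise_sd,vo2_noise_sd Per-sample measurement noise SDs.
#' @param target_fraction Fraction of HRmax that terminates the test.
#' @param rest_duration_s,recovery_duration_s,stage_duration_s Phase
#'   durations (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param warmup_delta First-stage heart-rate elevation above rest (bpm).
#' @param crossing_stages Stages among which the target-crossing stage is
#'   drawn uniformly.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config(n = 10)
sim_config <- function(n = 69,
                       prop_men = 42 / 69,
                       age_mean = c(woman = 21.7, man = 21.7),
                       age_sd = c(woman = 3.6, man = 3.4),
                       age_range = c(18, 40),
                       mass_mean = c(woman = 63.5, man = 72.0),
                       mass_sd = c(woman = 14.8, man = 7.3),
                       height_mean = c(woman = 1.64, man = 1.77),
                       height_sd = c(woman = 0.06, man = 0.07),
                       pa_probs = list(
                         woman = c(15, 8, 4) / 27,
                         man = c(3, 24, 15) / 42
                       ),
                       smoker_prob = 0.1,
                       hr_rest_mean = c(woman = 81, man = 68),
                       hr_rest_sd = c(woman = 11, man = 11),
                       hr_rest_range = c(45, 95),
                       vo2_rest_mean = c(woman = 3.4, man = 3.7),
                       vo2_rest_sd = c(woman = 0.7, man = 0.65),
                       hrr60_mean = 37, hrr60_sd = 11,
                       hrr60_range = c(19, 63),
                       outcome_noise_sd = 4.78,
                       hr_noise_sd = 2, vo2_noise_sd = 1,
                       target_fraction = 0.8,
                       rest_duration_s = 120,
                       recovery_duration_s = 120,
                       stage_duration_s = 60,
                       sample_rate_hz = 1,
                       warmup_delta = 20,
                       crossing_stages = 5:10) {
  cfg <- as.list(environment())
  for (p in cfg$pa_probs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_validation("pa_probs must be non-negative and sum to 1 per sex")
    }
  }
  sds <- c(
    age_sd, mass_sd, height_sd, hr_rest_sd, vo2_rest_sd,
    hrr60_sd, outcome_noise_sd, hr_noise_sd, vo2_noise_sd
  )
  if (any(sds < 0)) stop_validation("all sd parameters must be non-negative")
  if (n < 0) stop_validation("n must be non-negative")
  structure(cfg, class = "sim_config")
}

cohort_cols <- c(
  "participant_id", "sex", "age", "age_class", "body_mass", "height", "bmi",
  "smoker", "pa_level", "fitness_class", "hr_rest", "vo2_rest", "hr_max",
  "true_hrr60", "true_vo2max", "crossing_stage"
)

#' Sample a synthetic cohort
#'
#' Draws participants with profile attributes and physiological ground
#' truth: true HRR60 (truncated normal) and true VO2max generated from the
#' published equation's mean structure plus outcome noise. The per-
#' participant upper HRR60 bound is additionally capped at 90% of the gap
#' between the termination heart rate and rest, so a one-minute
#' mono-exponential recovery toward rest can realize it.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with one row per participant; ground-truth columns are
#'   prefixed `true_`.
#' @export
#' @examples
#' sample_cohort(sim_config(n = 5), seed = 1)
sample_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) stop_validation("config must be a sim_config")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  if (n == 0) {
    return(as_tibble(setNames(
      lapply(cohort_cols, function(x) logical(0)), cohort_cols
    ))[0, ])
  }
  n_men <- round(n * config$prop_men)
  sex <- c(rep("man", n_men), rep("woman", n - n_men))
  per_sex <- function(param) unname(param[sex])

  age <- rtnorm(n, per_sex(config$age_mean), per_sex(config$age_sd),
    config$age_range[1], config$age_range[2]
  )
  body_mass <- rtnorm(n, per_sex(config$mass_mean), per_sex(config$mass_sd), 40, 130)
  height <- rtnorm(n, per_sex(config$height_mean), per_sex(config$height_sd), 1.40, 2.10)
  bmi <- body_mass / height^2
  pa_level <- map_dbl(sex, function(s) {
    sample.int(3, 1, prob = config$pa_probs[[s]])
  })
  smoker <- runif(n) < config$smoker_prob
  hr_rest <- rtnorm(n, per_sex(config$hr_rest_mean), per_sex(config$hr_rest_sd),
    config$hr_rest_range[1], config$hr_rest_range[2]
  )
  vo2_rest <- rtnorm(n, per_sex(config$vo2_rest_mean), per_sex(config$vo2_rest_sd), 2, 6)
  hrm <- hr_max(age)
  hr_end <- config$target_fraction * hrm
  hrr_hi <- pmin(config$hrr60_range[2], 0.9 * (hr_end - hr_rest))
  true_hrr60 <- rtnorm(n, config$hrr60_mean, config$hrr60_sd,
    config$hrr60_range[1], hrr_hi
  )
  mu <- vo2max_equation(true_hrr60, sex, pa_level)
  true_vo2max <- rtnorm(n, mu, config$outcome_noise_sd, lo = vo2_rest + 8)
  tibble(
    participant_id = seq_len(n),
    sex = sex,
    age = age,
    age_class = age_class_of(age),
    body_mass = body_mass,
    height = height,
    bmi = bmi,
    smoker = smoker,
    pa_level = as.integer(pa_level),
    fitness_class = fitness_class_of(pa_level),
    hr_rest = hr_rest,
    vo2_rest = vo2_rest,
    hr_max = hrm,
    true_hrr60 = true_hrr60,
    true_vo2max = true_vo2max,
    crossing_stage = sample(config$crossing_stages, n, replace = TRUE)
  )
}

solve_recovery_tau <- function(hrr60, hr_end, hr_rest, window = 55:60) {
  q <- 1 - hrr60 / (hr_end - hr_rest)
  if (q <= 0 || q >= 1) {
    stop_validation("true_hrr60 must lie strictly between 0 and hr_end - hr_rest")
  }
  f <- function(tau) mean(exp(-window / tau)) - q
  uniroot(f, lower = 1, upper = 5000, tol = 1e-10)$root
}

#' Simulate one test session
#'
#' Generates a phase-labelled time series for one synthetic participant:
#' rest at the resting values, stages whose steady-state heart rate rises
#' linearly with stage index and is calibrated so the crossing stage lands
#' exactly on the termination target (`target_fraction x HRmax`), per-sample
#' VO2 on the line through (hr_rest, vo2_rest) and (HRmax, true VO2max), and
#' a mono-exponential heart-rate recovery whose time constant is back-solved
#' so the realized last-5-s-window HRR60 equals the participant's true
#' HRR60. Gaussian measurement noise is added per sample; VO2 is not
#' recorded during recovery.
#'
#' @param participant One cohort row from [sample_cohort()] (data frame or
#'   list with the cohort columns).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Session tibble with columns `time_s`, `hr_bpm`, `vo2_mlkgmin`,
#'   `phase`.
#' @export
#' @examples
#' cfg <- sim_config(n = 1, hr_noise_sd = 0, vo2_noise_sd = 0)
#' p <- sample_cohort(cfg, seed = 1)
#' sess <- simulate_session(p, cfg)
#' head(sess)
simulate_session <- function(participant, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(as_tibble(participant)[1, ])
  dt <- 1 / config$sample_rate_hz
  target <- config$target_fraction * p$hr_max
  k <- p$crossing_stage
  max_stages <- max(config$crossing_stages)
  if (k > max_stages) stop_validation("crossing_stage exceeds the schedule length")
  hr_stage1 <- p$hr_rest + config$warmup_delta
  if (hr_stage1 >= target && k > 1) {
    stop_validation("first-stage heart rate already exceeds the target")
  }
  inc <- if (k > 1) (target - hr_stage1) / (k - 1) else 0
  steady <- hr_stage1 + (seq_len(k) - 1) * inc
  s <- (p$true_vo2max - p$vo2_rest) / (p$hr_max - p$hr_rest)

  t_rest <- seq(0, config$rest_duration_s - dt, by = dt)
  rest <- tibble(
    time_s = t_rest,
    hr_bpm = p$hr_rest + rnorm(length(t_rest), 0, config$hr_noise_sd),
    vo2_mlkgmin = p$vo2_rest + rnorm(length(t_rest), 0, config$vo2_noise_sd),
    phase = "rest"
  )

  stage_list <- map(seq_len(k), function(j) {
    t0 <- config$rest_duration_s + (j - 1) * config$stage_duration_s
    tj <- seq(t0, t0 + config$stage_duration_s - dt, by = dt)
    tibble(
      time_s = tj,
      hr_bpm = steady[j] + rnorm(length(tj), 0, config$hr_noise_sd),
      vo2_mlkgmin = p$vo2_rest + s * (steady[j] - p$hr_rest) +
        rnorm(length(tj), 0, config$vo2_noise_sd),
      phase = paste0("stage_", j)
    )
  })

  stage_end <- config$rest_duration_s + k * config$stage_duration_s - dt
  tau <- solve_recovery_tau(p$true_hrr60, target, p$hr_rest)
  t_rel <- seq(dt, config$recovery_duration_s, by = dt)
  recovery <- tibble(
    time_s = stage_end + t_rel,
    hr_bpm = p$hr_rest + (target - p$hr_rest) * exp(-t_rel / tau) +
      rnorm(length(t_rel), 0, config$hr_noise_sd),
    vo2_mlkgmin = NA_real_,
    phase = "recovery"
  )

  bind_rows(rest, bind_rows(stage_list), recovery)
}

#' Simulate and analyze every session of a cohort
#'
#' Convenience wrapper: simulates one session per participant and runs
#' [analyze_session()] on each, binding the estimates onto the cohort.
#'
#' @param cohort A [sample_cohort()] tibble.
#' @param config The [sim_config()] used to generate the cohort.
#' @param seed Optional integer seed.
#' @return The cohort tibble with measured columns appended: `vo2max`
#'   (session-estimated), `hrr60`, `fit_r2`, `hr_rest_meas`, `vo2_rest_meas`.
#' @export
simulate_cohort_sessions <- function(cohort, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- map(seq_len(nrow(cohort)), function(i) {
    sess <- simulate_session(cohort[i, ], config)
    a <- analyze_session(sess, age = cohort$age[i])
    tibble(
      vo2max = a$vo2max, hrr60 = a$hrr60, fit_r2 = a$r2,
      hr_rest_meas = a$hr_rest, vo2_rest_meas = a$vo2_rest
    )
  })
  bind_cols(cohort, bind_rows(res))
}

#' End-to-end validation study on synthetic data
#'
#' Reproduces the two-group design: a cohort is sampled and measured via
#' simulated sessions, split into an equation-derivation group and a
#' validation group, the prediction equation is refit by backward
#' elimination on the derivation group, applied to the validation group,
#' and the measured-vs-predicted agreement battery is run.
#'
#' @param config A [sim_config()] (n >= 20).
#' @param seed Optional integer seed.
#' @param n_equation Size of the derivation group (default 30).
#' @param candidates Candidate predictors for the refit.
#' @param alpha Retention threshold.
#' @return List of class `validation_study`: `cohort` (with group and
#'   measured columns), `model` (the refit), `agreement` (the report).
#' @export
run_validation_study <- function(config = sim_config(), seed = NULL,
                                 n_equation = 30,
                                 candidates = c(
                                   "sex", "body_mass", "height", "bmi",
                                   "pa_level", "hrr60"
                                 ),
                                 alpha = 0.05) {
  if (config$n < 20) stop_validation("end-to-end study needs n >= 20")
  if (n_equation < length(candidates) + 2 || n_equation > config$n - 3) {
    stop_validation("n_equation leaves too few records in one of the groups")
  }
  if (!is.null(seed)) set.seed(seed)
  cohort <- sample_cohort(config)
  measured <- simulate_cohort_sessions(cohort, config)
  grp <- sample(rep(c("equation", "validation"),
    c(n_equation, config$n - n_equation)
  ))
  measured$group <- grp
  eq <- measured |> filter(.data$group == "equation")
  val <- measured |> filter(.data$group == "validation")
  model <- backward_stepwise(eq,
    outcome = "vo2max", candidates = candidates, alpha = alpha
  )
  val <- predict_vo2max(val, model)
  report <- validate_agreement(val, measured = vo2max, predicted = vo2max_pred)
  structure(
    list(cohort = measured, model = model, agreement = report),
    class = "validation_study"
  )
}

#' @export
print.validation_study <- function(x, ...) {
  cat("Synthetic validation study\n")
  print(x$model)
  print(x$agreement)
  invisible(x)
}
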