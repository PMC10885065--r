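# Protocol individualization: ponderation-based step height, progressive
# cadence schedule, age-predicted HRmax targets and termination logic.

ponderation_tables <- list(
  sex = c(woman = 0.5, man = 1),
  age_class = c(senior = 0, adult = 0.5, young = 1),
  fitness_class = c(
    insufficiently_active = 0,
    moderately_active = 0.5,
    vigorously_active = 1
  ),
  smoker = c(yes = 0, no = 0.5)
)

lookup_factor <- function(x, table, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% names(table)
  if (any(bad)) {
    stop_validation(sprintf(
      "%s must be one of: %s (got %s)",
      what, paste(names(table), collapse = ", "),
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  if (anyNA(x)) stop_validation(sprintf("%s contains missing values", what))
  unname(table[x])
}

bmi_ponderation <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE) || anyNA(bmi)) {
    stop_validation("bmi must be positive and non-missing")
  }
  dplyr::case_when(bmi < 25 ~ 0.5, bmi < 30 ~ 0, TRUE ~ -0.5)
}

#' Classify age in years into the protocol's age classes
#'
#' Default cut-offs: young < 35, adult 35--64, senior >= 65.
#'
#' @param age Age in years (> 0).
#' @param cutoffs Length-2 numeric: lower bounds of the adult and senior
#'   classes.
#' @return Character vector in `{"young", "adult", "senior"}`.
#' @export
#' @examples
#' age_class_of(c(22, 50, 70))
age_class_of <- function(age, cutoffs = c(adult = 35, senior = 65)) {
  if (any(age <= 0, na.rm = TRUE)) stop_validation("age must be positive")
  dplyr::case_when(
    age < cutoffs[[1]] ~ "young",
    age < cutoffs[[2]] ~ "adult",
    TRUE ~ "senior"
  )
}

#' Map IPAQ physical-activity level to the protocol's fitness class
#'
#' Level 1 maps to insufficiently active, 2 to moderately active and 3 to
#' vigorously active. The mapping is a convenience default; a directly
#' assessed fitness class can always be supplied instead.
#'
#' @param pa_level Integer vector in \{1, 2, 3\}.
#' @return Character vector of fitness classes.
#' @export
#' @examples
#' fitness_class_of(1:3)
fitness_class_of <- function(pa_level) {
  if (any(!pa_level %in% 1:3, na.rm = TRUE)) {
    stop_validation("pa_level must be in {1, 2, 3}")
  }
  c("insufficiently_active", "moderately_active", "vigorously_active")[pa_level]
}

prepare_profile <- function(data) {
  d <- as_tibble(data)
  check_columns(d, c("sex", "smoker"), "participant profile")
  if (!"age_class" %in% names(d)) {
    check_columns(d, "age", "participant profile (needs age or age_class)")
    d$age_class <- age_class_of(d$age)
  }
  if (!"fitness_class" %in% names(d)) {
    check_columns(d, "pa_level", "participant profile (needs fitness_class or pa_level)")
    d$fitness_class <- fitness_class_of(d$pa_level)
  }
  if (!"bmi" %in% names(d)) {
    check_columns(d, c("body_mass", "height"), "participant profile (needs bmi or body_mass + height)")
    d$bmi <- d$body_mass / d$height^2
  } else if (all(c("body_mass", "height") %in% names(d))) {
    implied <- d$body_mass / d$height^2
    off <- abs(implied - d$bmi) > 0.1
    if (any(off, na.rm = TRUE)) {
      warn(sprintf(
        "%d profile(s) have bmi inconsistent with body_mass/height^2 by > 0.1 kg/m^2",
        sum(off, na.rm = TRUE)
      ))
    }
  }
  d
}

smoker_ponderation <- function(smoker) {
  if (is.logical(smoker)) {
    if (anyNA(smoker)) stop_validation("smoker contains missing values")
    return(ifelse(smoker, 0, 0.5))
  }
  lookup_factor(smoker, ponderation_tables$smoker, "smoker")
}

#' Ponderation score and individualized step height
#'
#' Each profile is scored on five factors: sex (woman 0.5, man 1), age class
#' (senior 0, adult 0.5, young 1), fitness class (insufficiently active 0,
#' moderately active 0.5, vigorously active 1), BMI band (< 25 -> 0.5,
#' 25 to < 30 -> 0, >= 30 -> -0.5) and smoking status (smoker 0, nonsmoker
#' 0.5). The step height is `4 x ponderation sum + 15` cm, clamped to
#' \[15, 40\] cm and rounded to the nearest centimetre. Fitter, lower-risk
#' profiles step higher so that everyone reaches the target heart rate within
#' the ten-minute cap.
#'
#' @param data Data frame of participant profiles with columns `sex`
#'   (woman/man), `smoker` (logical or yes/no), and either `age_class`
#'   (young/adult/senior) or `age` (years), either `fitness_class` or
#'   `pa_level` (1--3), and either `bmi` or `body_mass` (kg) + `height` (m).
#' @return The input tibble with `ponderation_sum` and `step_height_cm`
#'   appended.
#' @export
#' @examples
#' library(tibble)
#' step_height(tibble(
#'   sex = "man", age = 24, pa_level = 3, bmi = 22, smoker = FALSE
#' ))
step_height <- function(data) {
  d <- prepare_profile(data)
  score <- lookup_factor(d$sex, ponderation_tables$sex, "sex") +
    lookup_factor(d$age_class, ponderation_tables$age_class, "age_class") +
    lookup_factor(d$fitness_class, ponderation_tables$fitness_class, "fitness_class") +
    bmi_ponderation(d$bmi) +
    smoker_ponderation(d$smoker)
  height_cm <- round(pmin(40, pmax(15, 4 * score + 15)))
  as_tibble(data) |>
    mutate(ponderation_sum = !!score, step_height_cm = !!height_cm)
}

#' Age-predicted maximal heart rate (Tanaka formula)
#'
#' `HRmax = 208 - 0.7 x age`.
#'
#' @param age Age in years (> 0).
#' @return Predicted maximal heart rate in bpm.
#' @export
#' @examples
#' hr_max(20)
hr_max <- function(age) {
  if (any(age <= 0, na.rm = TRUE)) stop_validation("age must be positive")
  208 - 0.7 * age
}

#' Target (termination) heart rate
#'
#' The test terminates when heart rate reaches a fraction (default 80%) of
#' the age-predicted maximum.
#'
#' @param age Age in years.
#' @param fraction Fraction of HRmax in (0, 1\]; default 0.8.
#' @return Target heart rate in bpm.
#' @export
#' @examples
#' target_hr(20)
target_hr <- function(age, fraction = 0.8) {
  if (any(fraction <= 0 | fraction > 1)) {
    stop_validation("fraction must lie in (0, 1]")
  }
  fraction * hr_max(age)
}

#' Progressive cadence schedule
#'
#' Cadence starts at 15 cycles/min (0.25 Hz) and increases by 2.5 cycles/min
#' per stage up to 37.5 cycles/min, within the overall test cap (default ten
#' minutes, one-minute stages, giving ten stages).
#'
#' @param max_duration_min Maximum test duration in minutes.
#' @param stage_duration_s Stage length in seconds.
#' @param start_cpm,increment_cpm,max_cpm Cadence start, per-stage increment
#'   and cap, in cycles/min.
#' @return Tibble with columns `stage`, `cadence_cpm`, `start_s`.
#' @export
#' @examples
#' cadence_schedule()
cadence_schedule <- function(max_duration_min = 10, stage_duration_s = 60,
                             start_cpm = 15, increment_cpm = 2.5,
                             max_cpm = 37.5) {
  if (max_duration_min <= 0 || stage_duration_s <= 0) {
    stop_validation("durations must be positive")
  }
  n_time <- floor(max_duration_min * 60 / stage_duration_s)
  n_cadence <- floor((max_cpm - start_cpm) / increment_cpm) + 1
  n <- min(n_time, n_cadence)
  if (n < 1) stop_validation("schedule admits no stages")
  tibble(
    stage = seq_len(n),
    cadence_cpm = start_cpm + (seq_len(n) - 1) * increment_cpm,
    start_s = (seq_len(n) - 1) * stage_duration_s
  )
}

#' Stage cadence for given stage indices
#' @param stage Stage index (1-based).
#' @inheritParams cadence_schedule
#' @return Cadence in cycles/min.
#' @export
stage_cadence <- function(stage, start_cpm = 15, increment_cpm = 2.5) {
  start_cpm + (stage - 1) * increment_cpm
}

#' Test-termination decision over a heart-rate stream
#'
#' Scans a time-ordered heart-rate stream for the first sample at or above
#' the target heart rate. Operator flags (discomfort, failure to hold
#' cadence) are honoured as alternative stop reasons; the earliest event
#' wins. If nothing triggers, the test is `completed`.
#'
#' @param data Data frame with columns `time_s` and `hr_bpm`, time-ordered.
#' @param target Target heart rate in bpm.
#' @param flags Optional data frame of operator events with columns `time_s`
#'   and `reason` (`"discomfort"` or `"cadence_failure"`).
#' @return One-row tibble: `reason` (one of `target_reached`, `discomfort`,
#'   `cadence_failure`, `completed`), `time_s`, `hr_bpm` (the triggering
#'   sample, or the final sample when completed).
#' @export
#' @examples
#' library(tibble)
#' termination_check(tibble(time_s = 1:5, hr_bpm = c(120, 135, 150, 158, 160)),
#'   target = 155
#' )
termination_check <- function(data, target, flags = NULL) {
  check_columns(data, c("time_s", "hr_bpm"), "heart-rate stream")
  if (nrow(data) == 0) stop_validation("heart-rate stream is empty")
  if (is.unsorted(data$time_s, strictly = FALSE)) {
    stop_validation("heart-rate stream must be time-ordered")
  }
  events <- tibble(
    reason = character(), time_s = numeric(), hr_bpm = numeric()
  )
  hit <- which(data$hr_bpm >= target)
  if (length(hit) > 0) {
    i <- hit[1]
    events <- add_row(events,
      reason = "target_reached",
      time_s = data$time_s[i], hr_bpm = data$hr_bpm[i]
    )
  }
  if (!is.null(flags) && nrow(flags) > 0) {
    check_columns(flags, c("time_s", "reason"), "operator flags")
    bad <- !flags$reason %in% c("discomfort", "cadence_failure")
    if (any(bad)) stop_validation("flag reason must be discomfort or cadence_failure")
    hr_at <- map_dbl(flags$time_s, function(t) {
      before <- which(data$time_s <= t)
      if (length(before) == 0) data$hr_bpm[1] else data$hr_bpm[max(before)]
    })
    events <- bind_rows(events, tibble(
      reason = flags$reason, time_s = flags$time_s, hr_bpm = hr_at
    ))
  }
  if (nrow(events) == 0) {
    n <- nrow(data)
    return(tibble(
      reason = "completed", time_s = data$time_s[n], hr_bpm = data$hr_bpm[n]
    ))
  }
  events |> arrange(.data$time_s) |> slice(1)
}
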