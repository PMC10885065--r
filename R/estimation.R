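# Session reduction and VO2max estimation: averaging windows for rest, stage
# ends and recovery; the individual HR-VO2 regression; extrapolation to
# age-predicted HRmax.

session_cols <- c("time_s", "hr_bpm", "vo2_mlkgmin", "phase")

validate_session <- function(session) {
  check_columns(session, session_cols, "session time series")
  if (nrow(session) == 0) stop_validation("session time series is empty")
  if (is.unsorted(session$time_s, strictly = TRUE)) {
    stop_validation("session time_s must be strictly increasing")
  }
  ok <- grepl("^(rest|recovery|stage_[0-9]+)$", session$phase)
  if (!all(ok)) {
    stop_validation(sprintf(
      "unknown phase label(s): %s",
      paste(unique(session$phase[!ok]), collapse = ", ")
    ))
  }
  if (any(session$hr_bpm <= 0, na.rm = TRUE)) {
    stop_validation("hr_bpm must be positive")
  }
  invisible(session)
}

phase_window <- function(session, phase, width) {
  rows <- session |> filter(.data$phase == !!phase)
  if (nrow(rows) == 0) return(rows)
  end <- max(rows$time_s)
  rows |> filter(.data$time_s >= end - width)
}

#' Resting heart rate and oxygen uptake
#'
#' Arithmetic means of heart rate and VO2 over the final 60 s of the rest
#' phase (closed window; a sample exactly on the window boundary is
#' included).
#'
#' @param session Session tibble with columns `time_s`, `hr_bpm`,
#'   `vo2_mlkgmin`, `phase` (see [read_session_csv()]).
#' @return One-row tibble with `hr_rest` (bpm) and `vo2_rest`
#'   (mL·kg⁻¹·min⁻¹).
#' @export
resting_values <- function(session) {
  validate_session(session)
  rest <- session |> filter(.data$phase == "rest")
  if (nrow(rest) == 0 || diff(range(rest$time_s)) < 60) {
    stop_insufficient("rest phase must span at least 60 s")
  }
  w <- phase_window(session, "rest", 60)
  tibble(
    hr_rest = mean(w$hr_bpm),
    vo2_rest = mean(w$vo2_mlkgmin, na.rm = TRUE)
  )
}

#' Stage-end summaries
#'
#' One row per stage: the mean heart rate and VO2 over the last 5 s of the
#' stage (closed window). A warning is raised for stages contributing fewer
#' than 3 samples to the window.
#'
#' @inheritParams resting_values
#' @param start_cpm,increment_cpm Cadence parameters used to annotate each
#'   stage, see [stage_cadence()].
#' @return Tibble with columns `stage`, `cadence_cpm`, `hr`, `vo2`,
#'   `n_samples`.
#' @export
stage_endpoints <- function(session, start_cpm = 15, increment_cpm = 2.5) {
  validate_session(session)
  stages <- session |>
    filter(grepl("^stage_", .data$phase)) |>
    mutate(stage = as.integer(sub("^stage_", "", .data$phase)))
  if (nrow(stages) == 0) stop_insufficient("session contains no stage samples")
  out <- stages |>
    group_by(.data$stage) |>
    group_modify(function(rows, key) {
      end <- max(rows$time_s)
      w <- rows |> filter(.data$time_s >= end - 5)
      if (nrow(w) == 0) {
        stop_insufficient(sprintf("stage %d has no samples in its last-5-s window", key$stage))
      }
      tibble(
        hr = mean(w$hr_bpm),
        vo2 = mean(w$vo2_mlkgmin, na.rm = TRUE),
        n_samples = nrow(w)
      )
    }) |>
    ungroup() |>
    arrange(.data$stage) |>
    mutate(cadence_cpm = stage_cadence(.data$stage, start_cpm, increment_cpm)) |>
    select("stage", "cadence_cpm", "hr", "vo2", "n_samples")
  few <- out$n_samples < 3
  if (any(few)) {
    warn(sprintf(
      "stage(s) %s have fewer than 3 samples in the last-5-s window",
      paste(out$stage[few], collapse = ", ")
    ))
  }
  out
}

#' One-minute heart-rate recovery (HRR60)
#'
#' `hr_end` is the last-5-s average heart rate of the final stage (set
#' `hr_end_method = "last_sample"` to use the last pre-recovery sample
#' instead); `hr_60` is the mean heart rate over the \[55 s, 60 s\] window of
#' the first recovery minute, measured from the end of exercise;
#' `hrr60 = hr_end - hr_60`. A negative recovery is flagged, not rejected.
#'
#' @inheritParams resting_values
#' @param hr_end_method `"stage_average"` (default) or `"last_sample"`.
#' @return One-row tibble: `hr_end`, `hr_60`, `hrr60` (all bpm),
#'   `hrr60_flag` (TRUE when hrr60 < 0).
#' @export
recovery_summary <- function(session, hr_end_method = c("stage_average", "last_sample")) {
  hr_end_method <- match.arg(hr_end_method)
  validate_session(session)
  rec <- session |> filter(.data$phase == "recovery")
  if (nrow(rec) == 0) stop_insufficient("session contains no recovery samples")
  pre <- session |> filter(.data$phase != "recovery")
  rec0 <- if (nrow(pre) > 0) max(pre$time_s) else min(rec$time_s)
  if (max(rec$time_s) - rec0 < 60) {
    stop_insufficient("recovery phase must span at least 60 s")
  }
  hr_end <- if (hr_end_method == "stage_average") {
    stages <- session |> filter(grepl("^stage_", .data$phase))
    if (nrow(stages) == 0) stop_insufficient("no stage samples to define hr_end")
    last_stage <- max(as.integer(sub("^stage_", "", stages$phase)))
    w <- phase_window(session, paste0("stage_", last_stage), 5)
    mean(w$hr_bpm)
  } else {
    if (nrow(pre) == 0) stop_insufficient("no pre-recovery sample to define hr_end")
    pre$hr_bpm[nrow(pre)]
  }
  w60 <- rec |> filter(.data$time_s - rec0 >= 55, .data$time_s - rec0 <= 60)
  if (nrow(w60) == 0) {
    stop_insufficient("no recovery samples in the [55 s, 60 s] window")
  }
  hr_60 <- mean(w60$hr_bpm)
  hrr60 <- hr_end - hr_60
  if (hrr60 < 0) warn("negative HRR60 (heart rate rose during recovery); flagged")
  tibble(hr_end = hr_end, hr_60 = hr_60, hrr60 = hrr60, hrr60_flag = hrr60 < 0)
}

#' Assemble the points entering the individual HR-VO2 regression
#'
#' The resting point plus one point per stage (last-5-s averages).
#'
#' @inheritParams stage_endpoints
#' @param include_rest Include the resting point (default TRUE).
#' @return Tibble with columns `role` ("rest"/"stage"), `stage`, `hr`, `vo2`.
#' @export
session_points <- function(session, include_rest = TRUE,
                           start_cpm = 15, increment_cpm = 2.5) {
  pts <- stage_endpoints(session, start_cpm, increment_cpm) |>
    transmute(role = "stage", stage = .data$stage, hr = .data$hr, vo2 = .data$vo2)
  if (include_rest) {
    r <- resting_values(session)
    pts <- bind_rows(
      tibble(role = "rest", stage = NA_integer_, hr = r$hr_rest, vo2 = r$vo2_rest),
      pts
    )
  }
  pts
}

#' Fit the individual HR-VO2 regression
#'
#' Ordinary least squares of VO2 on heart rate over the resting point and
#' the stage-end points (`vo2 = intercept + slope x hr`). At least four
#' points (rest plus three stages, or four stages) are required. In
#' practice this line is nearly perfect (R² typically 0.97--0.99), which is
#' what licenses extrapolating it to HRmax.
#'
#' @param points Data frame with columns `hr` and `vo2`, e.g. from
#'   [session_points()].
#' @return An object of class `hr_vo2_fit` with elements `slope`,
#'   `intercept`, `r2`, `n_points`, the underlying `lm` fit and the points.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_hr_vo2 <- function(points) {
  check_columns(points, c("hr", "vo2"), "regression points")
  pts <- as_tibble(points) |> filter(!is.na(.data$hr), !is.na(.data$vo2))
  if (nrow(pts) < 4) {
    stop_insufficient("HR-VO2 regression needs at least 4 points (rest + 3 stages)")
  }
  if (sd(pts$hr) == 0) {
    abort("degenerate fit: heart rate has zero variance across points",
      class = "stepcap_degenerate_fit_error"
    )
  }
  fit <- lm(vo2 ~ hr, data = pts)
  # a noise-free session yields an exact line; that summary warning is benign
  s <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(coef(fit)[["hr"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r2 = s$r.squared,
      n_points = nrow(pts),
      model = fit,
      points = pts
    ),
    class = "hr_vo2_fit"
  )
}

#' @export
print.hr_vo2_fit <- function(x, ...) {
  cat("Individual HR-VO2 regression\n")
  cat(sprintf(
    "  vo2 = %.4f + %.4f x hr   (n = %d points, R^2 = %.4f)\n",
    x$intercept, x$slope, x$n_points, x$r2
  ))
  invisible(x)
}

#' @export
tidy.hr_vo2_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("intercept", "hr"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @export
glance.hr_vo2_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    sigma = suppressWarnings(summary(x$model))$sigma,
    nobs = x$n_points
  )
}

#' @export
autoplot.hr_vo2_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$hr, y = .data$vo2)) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Heart rate [bpm]",
      y = expression(VO[2] ~ "[mL·kg"^-1 * "·min"^-1 * "]"),
      title = sprintf("HR–VO2 regression (R² = %.3f)", object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Extrapolate the HR-VO2 regression to maximal heart rate
#'
#' VO2max is the fitted line evaluated at the (age-predicted) maximal heart
#' rate. A warning is raised when `hr_max` does not exceed the largest
#' observed heart rate, since the estimate is then not an extrapolation.
#'
#' @param fit An [fit_hr_vo2()] object.
#' @param hr_max Maximal heart rate in bpm, typically [hr_max()].
#' @return Estimated VO2max in mL·kg⁻¹·min⁻¹.
#' @export
estimate_vo2max <- function(fit, hr_max) {
  if (!inherits(fit, "hr_vo2_fit")) stop_validation("fit must be an hr_vo2_fit object")
  if (any(hr_max <= max(fit$points$hr))) {
    warn("hr_max does not exceed the observed heart-rate range; value is an interpolation")
  }
  fit$intercept + fit$slope * hr_max
}

#' Full single-session analysis
#'
#' Reduces one session to the quantities the method reports: resting values,
#' the HR-VO2 regression, the VO2max extrapolated to age-predicted HRmax,
#' and the one-minute heart-rate recovery.
#'
#' @inheritParams resting_values
#' @param age Participant age in years (drives the HRmax prediction).
#' @param include_rest Include the resting point in the regression.
#' @param hr_end_method Passed to [recovery_summary()].
#' @return One-row tibble: `hr_rest`, `vo2_rest`, `n_points`, `slope`,
#'   `intercept`, `r2`, `hr_max`, `vo2max`, `hr_end`, `hr_60`, `hrr60`.
#' @export
analyze_session <- function(session, age, include_rest = TRUE,
                            hr_end_method = "stage_average") {
  rest <- resting_values(session)
  pts <- session_points(session, include_rest = include_rest)
  fit <- fit_hr_vo2(pts)
  hrm <- hr_max(age)
  rec <- recovery_summary(session, hr_end_method = hr_end_method)
  tibble(
    hr_rest = rest$hr_rest, vo2_rest = rest$vo2_rest,
    n_points = fit$n_points, slope = fit$slope, intercept = fit$intercept,
    r2 = fit$r2, hr_max = hrm,
    vo2max = estimate_vo2max(fit, hrm),
    hr_end = rec$hr_end, hr_60 = rec$hr_60, hrr60 = rec$hrr60
  )
}
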