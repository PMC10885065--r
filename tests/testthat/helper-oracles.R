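# Independent oracles and fixture builders used across the suite.

# OLS by explicit normal equations (independent of lm's QR route).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  list(slope = slope, intercept = intercept, r2 = 1 - sse / sst)
}

# Paired t by explicit summation formulas.
paired_t_oracle <- function(m, p, conf_level = 0.95) {
  d <- m - p
  n <- length(d)
  se <- sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n)
  t_stat <- mean(d) / se
  crit <- qt(1 - (1 - conf_level) / 2, n - 1)
  list(
    mean_diff = mean(d), t_stat = t_stat, df = n - 1,
    p_value = 2 * pt(-abs(t_stat), n - 1),
    ci_lower = mean(d) - crit * se, ci_upper = mean(d) + crit * se
  )
}

# ICC(A,1) via stats::aov's ANOVA decomposition (independent of the
# package's direct summation implementation).
icc_oracle <- function(m, p) {
  n <- length(m)
  df <- data.frame(
    y = c(m, p),
    subject = factor(rep(seq_len(n), 2)),
    method = factor(rep(c("m", "p"), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + method, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["method", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# Deterministic session builder: constant-rate sampling, constant or
# supplied per-phase heart rates, VO2 linear in HR unless overridden.
make_session <- function(hr_rest = 70, vo2_rest = 3.5,
                         stage_hr = c(100, 115, 130, 145),
                         slope = 0.25,
                         rest_dur = 120, stage_dur = 60, recovery_dur = 120,
                         recovery_hr = NULL, dt = 1) {
  t_rest <- seq(0, rest_dur - dt, by = dt)
  rest <- tibble::tibble(
    time_s = t_rest, hr_bpm = hr_rest,
    vo2_mlkgmin = vo2_rest, phase = "rest"
  )
  stages <- purrr::map(seq_along(stage_hr), function(j) {
    t0 <- rest_dur + (j - 1) * stage_dur
    tj <- seq(t0, t0 + stage_dur - dt, by = dt)
    tibble::tibble(
      time_s = tj, hr_bpm = stage_hr[j],
      vo2_mlkgmin = vo2_rest + slope * (stage_hr[j] - hr_rest),
      phase = paste0("stage_", j)
    )
  })
  end <- rest_dur + length(stage_hr) * stage_dur - dt
  t_rel <- seq(dt, recovery_dur, by = dt)
  hr_end <- stage_hr[length(stage_hr)]
  rec_hr <- if (is.null(recovery_hr)) {
    hr_rest + (hr_end - hr_rest) * exp(-t_rel / 60)
  } else {
    recovery_hr(t_rel)
  }
  recovery <- tibble::tibble(
    time_s = end + t_rel, hr_bpm = rec_hr,
    vo2_mlkgmin = NA_real_, phase = "recovery"
  )
  dplyr::bind_rows(rest, dplyr::bind_rows(stages), recovery)
}

# Random IPAQ response generator for property tests.
random_ipaq <- function(n = 1) {
  tibble::tibble(
    vigorous_days = sample(0:7, n, replace = TRUE),
    vigorous_min = round(runif(n, 0, 120)),
    moderate_days = sample(0:7, n, replace = TRUE),
    moderate_min = round(runif(n, 0, 120)),
    walking_days = sample(0:7, n, replace = TRUE),
    walking_min = round(runif(n, 0, 120))
  )
}
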