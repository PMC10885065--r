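# Measured-vs-predicted agreement battery: paired t, Cohen's d with
# qualitative descriptors, two-way mixed absolute-agreement ICC, and
# Bland-Altman limits of agreement with the >= 80% coverage criterion.

pull_pair <- function(data, measured, predicted) {
  m <- dplyr::pull(data, {{ measured }})
  p <- dplyr::pull(data, {{ predicted }})
  if (length(m) != length(p)) stop_validation("measured and predicted must have equal length")
  ok <- is.finite(m) & is.finite(p)
  if (!all(ok)) stop_validation("measured/predicted values must be finite")
  if (length(m) < 3) stop_insufficient("agreement statistics need at least 3 pairs")
  list(m = m, p = p, d = m - p, n = length(m))
}

#' Paired t-test of measured vs predicted values
#'
#' Mean paired difference (measured - predicted) with its 95% confidence
#' interval, t statistic on n - 1 degrees of freedom and two-sided p-value.
#' With zero variance of the differences the statistic is reported as 0
#' (all differences zero) or +/-Inf, with `degenerate = TRUE`.
#'
#' @param data Data frame of paired values.
#' @param measured,predicted Columns holding the two measurements
#'   (tidy-eval; default `measured`, `predicted`).
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `mean_diff`, `ci_lower`, `ci_upper`, `t_stat`,
#'   `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(data, measured = measured, predicted = predicted,
                     conf_level = 0.95) {
  pp <- pull_pair(data, {{ measured }}, {{ predicted }})
  if (sd(pp$d) == 0) {
    md <- mean(pp$d)
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    return(tibble(
      mean_diff = md, ci_lower = md, ci_upper = md,
      t_stat = t_stat, df = pp$n - 1,
      p_value = if (md == 0) 1 else 0, degenerate = TRUE
    ))
  }
  tt <- t.test(pp$m, pp$p, paired = TRUE, conf.level = conf_level)
  tibble(
    mean_diff = unname(tt$estimate),
    ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, degenerate = FALSE
  )
}

#' Paired t statistic implied by a printed mean difference and CI
#'
#' Back-computes the t statistic from summary-level results (mean paired
#' difference with its confidence interval and the sample size), as needed
#' when only a results table is available:
#' `t = mean_diff / (half_width / t_crit)`.
#'
#' @param mean_diff Mean paired difference.
#' @param ci_lower,ci_upper Confidence-interval bounds.
#' @param n Number of pairs.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return The implied t statistic.
#' @export
#' @examples
#' paired_t_from_ci(-0.345, -2.767, 2.076, n = 39)
paired_t_from_ci <- function(mean_diff, ci_lower, ci_upper, n, conf_level = 0.95) {
  if (n < 2) stop_validation("n must be at least 2")
  half <- (ci_upper - ci_lower) / 2
  if (half <= 0) stop_validation("confidence interval must have positive width")
  se <- half / qt(1 - (1 - conf_level) / 2, df = n - 1)
  mean_diff / se
}

#' Qualitative descriptor for Cohen's d
#'
#' Bands: trivial (< 0.20), small (0.20--0.59), moderate (0.6--1.19),
#' large (1.2--1.99), very large (>= 2.0).
#'
#' @param d Effect size (sign ignored).
#' @return Ordered factor of descriptors.
#' @export
#' @examples
#' effect_size_label(c(0.04, 0.3, 1.5))
effect_size_label <- function(d) {
  cut(abs(d),
    breaks = c(-Inf, 0.2, 0.6, 1.2, 2, Inf),
    labels = c("trivial", "small", "moderate", "large", "very large"),
    right = FALSE, ordered_result = TRUE
  )
}

#' Cohen's d for paired measurements
#'
#' Absolute standardized mean difference. The `pooled_sd` variant divides by
#' `sqrt((sd_m^2 + sd_p^2) / 2)`; the `diff_sd` variant divides by the
#' standard deviation of the paired differences.
#'
#' @inheritParams paired_t
#' @param variant Denominator variant; default `"pooled_sd"`.
#' @return One-row tibble: `d`, `d_label`.
#' @export
cohens_d <- function(data, measured = measured, predicted = predicted,
                     variant = c("pooled_sd", "diff_sd")) {
  variant <- match.arg(variant)
  pp <- pull_pair(data, {{ measured }}, {{ predicted }})
  denom <- switch(variant,
    pooled_sd = sqrt((var(pp$m) + var(pp$p)) / 2),
    diff_sd = sd(pp$d)
  )
  if (denom == 0) {
    abort("undefined effect size: zero variance denominator",
      class = "stepcap_undefined_effect_error"
    )
  }
  d <- abs(mean(pp$d)) / denom
  tibble(d = d, d_label = effect_size_label(d))
}

#' Cohen's d from printed group summaries
#'
#' @param mean_x,sd_x,mean_y,sd_y Group means and standard deviations.
#' @param variant `"pooled_sd"` (default) uses `sqrt((sd_x^2 + sd_y^2)/2)`;
#'   `"diff_sd"` requires `sd_diff`.
#' @param sd_diff Standard deviation of the paired differences (only for
#'   `variant = "diff_sd"`).
#' @return One-row tibble: `d`, `d_label`.
#' @export
#' @examples
#' cohens_d_from_summary(41.14, 9.65, 41.48, 6.94)
cohens_d_from_summary <- function(mean_x, sd_x, mean_y, sd_y,
                                  variant = c("pooled_sd", "diff_sd"),
                                  sd_diff = NULL) {
  variant <- match.arg(variant)
  denom <- switch(variant,
    pooled_sd = sqrt((sd_x^2 + sd_y^2) / 2),
    diff_sd = {
      if (is.null(sd_diff)) stop_validation("sd_diff required for diff_sd variant")
      sd_diff
    }
  )
  if (denom == 0) {
    abort("undefined effect size: zero variance denominator",
      class = "stepcap_undefined_effect_error"
    )
  }
  d <- abs(mean_x - mean_y) / denom
  tibble(d = d, d_label = effect_size_label(d))
}

#' Qualitative descriptor for an ICC
#'
#' Bands: poor (< 0.5), moderate (0.5--0.75), good (0.75--0.90),
#' excellent (>= 0.90).
#'
#' @param icc Intraclass correlation value(s).
#' @return Ordered factor of descriptors.
#' @export
#' @examples
#' icc_label(0.759)
icc_label <- function(icc) {
  cut(icc,
    breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
    labels = c("poor", "moderate", "good", "excellent"),
    right = FALSE, ordered_result = TRUE
  )
}

#' Two-way mixed absolute-agreement ICC (single measure)
#'
#' ICC(A,1): single-measure intraclass correlation under a two-way mixed
#' model with the absolute-agreement definition, computed from the two-way
#' ANOVA mean squares (subjects x methods):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 methods.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `icc`, `icc_label`, `ms_rows`, `ms_cols`,
#'   `ms_error`.
#' @export
icc_absolute_agreement <- function(data, measured = measured, predicted = predicted) {
  pp <- pull_pair(data, {{ measured }}, {{ predicted }})
  x <- cbind(pp$m, pp$p)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0) {
    abort("undefined ICC: zero total variance", class = "stepcap_undefined_icc_error")
  }
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  tibble(
    icc = icc, icc_label = icc_label(icc),
    ms_rows = msr, ms_cols = msc, ms_error = mse
  )
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean difference (measured - predicted); the limits of
#' agreement are `bias +/- 1.96 x sd(differences)`. The coverage criterion
#' asks whether at least 80% of pairs fall within the limits (boundary
#' values count as within).
#'
#' @inheritParams paired_t
#' @param k Multiplier on the SD of differences (default 1.96).
#' @param pass_threshold Minimum within-limits percentage for
#'   `loa_pass` (default 80).
#' @return One-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `pct_within_loa`, `loa_pass`.
#' @export
bland_altman <- function(data, measured = measured, predicted = predicted,
                         k = 1.96, pass_threshold = 80) {
  pp <- pull_pair(data, {{ measured }}, {{ predicted }})
  bias <- mean(pp$d)
  s <- sd(pp$d)
  lo <- bias - k * s
  hi <- bias + k * s
  pct <- 100 * mean(pp$d >= lo & pp$d <= hi)
  tibble(
    bias = bias, sd_diff = s, loa_lower = lo, loa_upper = hi,
    pct_within_loa = pct, loa_pass = pct >= pass_threshold
  )
}

#' Run the full measured-vs-predicted agreement battery
#'
#' Combines [paired_t()], [cohens_d()], [icc_absolute_agreement()] and
#' [bland_altman()] into one report, as used to validate predicted against
#' measured VO2max.
#'
#' @inheritParams paired_t
#' @param d_variant Cohen's d denominator variant, see [cohens_d()].
#' @return An object of class `agreement_report` with [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
validate_agreement <- function(data, measured = measured, predicted = predicted,
                               d_variant = "pooled_sd", conf_level = 0.95) {
  pp <- pull_pair(data, {{ measured }}, {{ predicted }})
  pairs <- tibble(measured = pp$m, predicted = pp$p)
  structure(
    list(
      n = pp$n,
      t = paired_t(pairs, conf_level = conf_level),
      d = cohens_d(pairs, variant = d_variant),
      icc = icc_absolute_agreement(pairs),
      ba = bland_altman(pairs),
      d_variant = d_variant,
      pairs = pairs
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d pairs)\n", x$n))
  cat(sprintf(
    "  paired t: mean diff %.3f (95%% CI %.3f to %.3f), t = %.3f, df = %d, p = %.3f\n",
    x$t$mean_diff, x$t$ci_lower, x$t$ci_upper, x$t$t_stat, x$t$df, x$t$p_value
  ))
  cat(sprintf("  Cohen's d (%s): %.3f [%s]\n", x$d_variant, x$d$d, x$d$d_label))
  cat(sprintf("  ICC(A,1): %.3f [%s]\n", x$icc$icc, x$icc$icc_label))
  cat(sprintf(
    "  Bland-Altman: bias %.3f, LoA %.3f to %.3f, %.1f%% within (%s)\n",
    x$ba$bias, x$ba$loa_lower, x$ba$loa_upper, x$ba$pct_within_loa,
    if (x$ba$loa_pass) "pass" else "fail"
  ))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tibble(
    statistic = c(
      "mean_diff", "ci_lower", "ci_upper", "t_stat", "df", "p_value",
      "d", "icc", "bias", "sd_diff", "loa_lower", "loa_upper",
      "pct_within_loa"
    ),
    value = c(
      x$t$mean_diff, x$t$ci_lower, x$t$ci_upper, x$t$t_stat, x$t$df,
      x$t$p_value, x$d$d, x$icc$icc, x$ba$bias, x$ba$sd_diff,
      x$ba$loa_lower, x$ba$loa_upper, x$ba$pct_within_loa
    ),
    label = c(
      rep(NA_character_, 6), as.character(x$d$d_label),
      as.character(x$icc$icc_label), rep(NA_character_, 4),
      if (x$ba$loa_pass) "pass" else "fail"
    )
  )
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    nobs = x$n,
    mean_diff = x$t$mean_diff, p_value = x$t$p_value,
    d = x$d$d, d_label = as.character(x$d$d_label),
    icc = x$icc$icc, icc_label = as.character(x$icc$icc_label),
    bias = x$ba$bias, pct_within_loa = x$ba$pct_within_loa,
    loa_pass = x$ba$loa_pass
  )
}

#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- object$pairs |>
    mutate(
      avg = (.data$measured + .data$predicted) / 2,
      diff = .data$measured - .data$predicted
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$ba$loa_lower, object$ba$loa_upper),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Mean of measured and predicted VO2max",
      y = "Measured - predicted VO2max",
      title = sprintf(
        "Bland–Altman: bias %.2f, LoA [%.2f, %.2f], %.0f%% within",
        object$ba$bias, object$ba$loa_lower, object$ba$loa_upper,
        object$ba$pct_within_loa
      )
    ) +
    ggplot2::theme_minimal()
}
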