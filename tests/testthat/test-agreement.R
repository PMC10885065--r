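pairs_df <- function(m, p) tibble::tibble(measured = m, predicted = p)

test_that("paired t matches hand computation and the summation oracle", {
  # identical vectors: zero difference, zero t
  same <- pairs_df(c(40, 45, 50), c(40, 45, 50))
  out <- paired_t(same)
  expect_equal(out$mean_diff, 0)
  expect_equal(out$t_stat, 0)

  # 3-pair worked example: d = (2, 1, 1), t = (4/3) / (sd/sqrt(3)) = 4
  w <- pairs_df(c(40, 45, 50), c(38, 44, 49))
  out <- paired_t(w)
  expect_equal(out$mean_diff, 4 / 3)
  expect_equal(out$t_stat, 4, tolerance = 1e-12)
  expect_equal(out$df, 2)
  o <- paired_t_oracle(w$measured, w$predicted)
  expect_equal(out$p_value, o$p_value)
  expect_equal(out$ci_lower, o$ci_lower)
  expect_equal(out$ci_upper, o$ci_upper)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    m <- rnorm(n, 42, 8)
    p <- m + rnorm(n, 0.5, 3)
    got <- paired_t(pairs_df(m, p))
    o <- paired_t_oracle(m, p)
    expect_equal(got$t_stat, o$t_stat, tolerance = 1e-10)
    expect_equal(got$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(got$ci_lower, o$ci_lower, tolerance = 1e-10)
  }

  # constant nonzero difference: infinite t, flagged
  off <- pairs_df(c(40, 45, 50), c(39, 44, 49))
  out <- paired_t(off)
  expect_true(out$degenerate)
  expect_equal(out$t_stat, Inf)
})

test_that("the implied t from a printed mean difference and CI is recovered", {
  # printed validation-table summary: mean diff -0.345 (CI -2.767 to 2.076),
  # n = 39 implies t = -0.289
  t_implied <- paired_t_from_ci(-0.3455, -2.767, 2.076, n = 39)
  expect_equal(round(t_implied, 3), -0.289)
  # self-consistency: back out t from a computed CI
  set.seed(2)
  d <- pairs_df(rnorm(15, 40, 5), rnorm(15, 41, 5))
  ref <- paired_t(d)
  expect_equal(
    paired_t_from_ci(ref$mean_diff, ref$ci_lower, ref$ci_upper, 15),
    ref$t_stat,
    tolerance = 1e-10
  )
})

test_that("Cohen's d variants and descriptors behave as specified", {
  # identical vectors with spread: d = 0, trivial
  same <- pairs_df(c(40, 45, 50), c(40, 45, 50))
  out <- cohens_d(same)
  expect_equal(out$d, 0)
  expect_equal(as.character(out$d_label), "trivial")

  # mean difference 1 with unit pooled SD: d = 1, moderate
  one <- pairs_df(c(-1, 0, 1) + 1, c(-1, 0, 1))
  out <- cohens_d(one)
  expect_equal(out$d, 1)
  expect_equal(as.character(out$d_label), "moderate")

  # printed group summaries reproduce the published trivial effect
  tab <- cohens_d_from_summary(41.14, 9.65, 41.48, 6.94)
  expect_equal(round(tab$d, 2), 0.04)
  expect_equal(as.character(tab$d_label), "trivial")
  # the difference-SD variant on the same summaries gives ~0.05
  sd_diff <- (2.076 - (-2.767)) / 2 / qt(0.975, 38) * sqrt(39)
  alt <- cohens_d_from_summary(41.14, 9.65, 41.48, 6.94,
    variant = "diff_sd", sd_diff = sd_diff
  )
  expect_equal(round(alt$d, 2), 0.05)

  expect_error(
    cohens_d(pairs_df(rep(5, 3), rep(5, 3))),
    class = "stepcap_undefined_effect_error"
  )

  # descriptor bands are sharp at every boundary
  expect_equal(
    as.character(effect_size_label(c(0.19, 0.2, 0.59, 0.6, 1.19, 1.2, 1.99, 2, 3))),
    c("trivial", "small", "small", "moderate", "moderate", "large", "large",
      "very large", "very large")
  )
})

test_that("ICC(A,1) matches the ANOVA oracle and a frozen reference value", {
  # identical vectors: perfect agreement
  same <- pairs_df(c(40, 45, 50), c(40, 45, 50))
  out <- icc_absolute_agreement(same)
  expect_equal(out$icc, 1)
  expect_equal(as.character(out$icc_label), "excellent")

  # worked 5-pair dataset: value frozen from an independent two-way
  # absolute-agreement computation
  w <- pairs_df(
    c(40.2, 35.1, 48.7, 41.0, 44.4),
    c(38.5, 36.0, 46.2, 43.1, 42.9)
  )
  out <- icc_absolute_agreement(w)
  expect_equal(out$icc, 0.9200942897002943, tolerance = 1e-12)
  expect_equal(out$icc, icc_oracle(w$measured, w$predicted), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    m <- rnorm(n, 42, 8)
    p <- 0.8 * m + rnorm(n, 8, 3)
    got <- icc_absolute_agreement(pairs_df(m, p))
    expect_equal(got$icc, icc_oracle(m, p), tolerance = 1e-10)
  }

  # qualitative bands
  expect_equal(as.character(icc_label(0.759)), "good")
  expect_equal(
    as.character(icc_label(c(0.49, 0.5, 0.74, 0.75, 0.89, 0.9))),
    c("poor", "moderate", "moderate", "good", "good", "excellent")
  )
  expect_error(
    icc_absolute_agreement(pairs_df(rep(3, 4), rep(3, 4))),
    class = "stepcap_undefined_icc_error"
  )
})

test_that("Bland-Altman limits, coverage and the 80% criterion", {
  # constant offset: zero-width limits at the bias, everything within
  off <- pairs_df(c(40, 45, 50), c(38, 43, 48))
  out <- bland_altman(off)
  expect_equal(out$bias, 2)
  expect_equal(out$sd_diff, 0)
  expect_equal(out$pct_within_loa, 100)
  expect_true(out$loa_pass)

  # one extreme outlier among 20: 95% within, still a pass
  m <- seq(35, 54, length.out = 20)
  p <- m
  p[20] <- p[20] - 40
  out <- bland_altman(pairs_df(m, p))
  expect_equal(out$pct_within_loa, 95)
  expect_true(out$loa_pass)

  # Gaussian differences cover ~95% within 1.96 SD at large n
  set.seed(4)
  m <- rnorm(5000, 42, 6)
  p <- m + rnorm(5000, 0, 3)
  out <- bland_altman(pairs_df(m, p))
  expect_gt(out$pct_within_loa, 93)
  expect_lt(out$pct_within_loa, 97)
  expect_true(out$loa_lower <= out$bias & out$bias <= out$loa_upper)
  # limits symmetric about the bias
  expect_equal(out$bias - out$loa_lower, out$loa_upper - out$bias)
})

test_that("shifting both series leaves the difference-based battery unchanged", {
  set.seed(9)
  m <- rnorm(25, 41, 7)
  p <- m + rnorm(25, -0.3, 3)
  a <- validate_agreement(pairs_df(m, p))
  b <- validate_agreement(pairs_df(m + 50, p + 50))
  expect_equal(b$t$t_stat, a$t$t_stat)
  expect_equal(b$d$d, a$d$d)
  expect_equal(b$icc$icc, a$icc$icc)
  expect_equal(b$ba$bias, a$ba$bias)
  expect_equal(b$ba$pct_within_loa, a$ba$pct_within_loa)
})

test_that("the agreement report aggregates, prints, tidies and plots", {
  set.seed(12)
  m <- rnorm(39, 41.1, 9.6)
  p <- m + rnorm(39, -0.3, 7)
  rep <- validate_agreement(pairs_df(m, p))
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$n, 39)
  td <- tidy(rep)
  expect_true(all(c("mean_diff", "icc", "pct_within_loa") %in% td$statistic))
  expect_equal(td$value[td$statistic == "icc"], rep$icc$icc)
  gl <- glance(rep)
  expect_equal(gl$nobs, 39)
  expect_equal(gl$d, rep$d$d)
  expect_output(print(rep), "Bland-Altman")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_error(
    validate_agreement(pairs_df(c(1, 2), c(1, 2))),
    class = "stepcap_insufficient_data_error"
  )
})
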