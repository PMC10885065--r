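test_that("the published equation reproduces its printed coefficients", {
  # formal zero point gives the intercept
  expect_warning(v0 <- vo2max_equation(0, 0, 0), "pa_level")
  expect_equal(v0, 17.105)
  # sex gap at equal HRR60 and PA level
  expect_equal(
    vo2max_equation(40, 1, 2) - vo2max_equation(40, 0, 2), 8.563
  )
  # one PA level costs/gains 4.097
  expect_equal(
    vo2max_equation(40, 1, 3) - vo2max_equation(40, 1, 2), 4.097
  )
  expect_equal(vo2max_equation(38, 1, 2), 17.105 + 0.260 * 38 + 8.563 + 4.097 * 2)
  expect_equal(vo2max_equation(38, 1, 2), 43.742, tolerance = 1e-12)
  # strictly increasing in hrr60
  expect_true(all(diff(vo2max_equation(0:80, 1, 2)) > 0))
})

test_that("predict_vo2max evaluates models over cohort columns", {
  d <- tibble::tibble(
    hrr60 = c(38, 25), sex = c("man", "woman"), pa_level = c(2L, 1L)
  )
  out <- predict_vo2max(d)
  expect_equal(out$vo2max_pred[1], 43.742, tolerance = 1e-12)
  expect_equal(out$vo2max_pred[2], 17.105 + 0.26 * 25 + 4.097)
  # retained coefficients without matching columns are an error
  expect_error(
    predict_vo2max(tibble::tibble(hrr60 = 38, sex = 1)),
    class = "stepcap_model_error"
  )
  expect_warning(
    predict_vo2max(tibble::tibble(hrr60 = 38, sex = 1, pa_level = 5)),
    "pa_level"
  )
})

make_eq_cohort <- function(n, noise_sd, seed) {
  set.seed(seed)
  d <- tibble::tibble(
    sex = sample(0:1, n, replace = TRUE),
    body_mass = rnorm(n, 68, 10),
    height = rnorm(n, 1.72, 0.08),
    pa_level = sample(1:3, n, replace = TRUE),
    hrr60 = runif(n, 19, 63)
  )
  d$bmi <- d$body_mass / d$height^2
  d$vo2max <- vo2max_equation(d$hrr60, d$sex, d$pa_level) + rnorm(n, 0, noise_sd)
  d
}

test_that("backward elimination recovers the generating model", {
  # near-noiseless outcome: the three true predictors are retained with
  # the generating coefficients
  d <- make_eq_cohort(60, noise_sd = 1e-6, seed = 11)
  m <- backward_stepwise(d)
  expect_setequal(m$retained, c("sex", "pa_level", "hrr60"))
  expect_equal(m$coefficients[["intercept"]], 17.105, tolerance = 1e-4)
  expect_equal(m$coefficients[["hrr60"]], 0.260, tolerance = 1e-4)
  expect_equal(m$coefficients[["sex"]], 8.563, tolerance = 1e-4)
  expect_equal(m$coefficients[["pa_level"]], 4.097, tolerance = 1e-4)
  expect_true(all(m$pvalues[m$retained] < 0.05))

  # realistic noise (SD 4.78) on cohorts of 30: the exact generating set
  # {sex, pa_level, hrr60} is recovered in the large majority of seeds
  hits <- vapply(1:20, function(s) {
    m30 <- backward_stepwise(make_eq_cohort(30, noise_sd = 4.78, seed = s))
    setequal(m30$retained, c("sex", "pa_level", "hrr60"))
  }, logical(1))
  expect_gte(mean(hits), 0.6)

  # a single candidate uncorrelated with the outcome: intercept-only model
  set.seed(5)
  junk <- tibble::tibble(vo2max = rnorm(40, 40, 5), noise = rnorm(40))
  m0 <- backward_stepwise(junk, candidates = "noise")
  expect_equal(m0$retained, character(0))
  expect_equal(names(m0$coefficients), "intercept")
  expect_equal(m0$coefficients[["intercept"]], mean(junk$vo2max))
})

test_that("SEE is the residual standard error with n - p - 1 denominator", {
  d <- make_eq_cohort(50, noise_sd = 4, seed = 21)
  m <- backward_stepwise(d, candidates = c("sex", "pa_level", "hrr60"))
  fitted <- predict_vo2max(d, m)$vo2max_pred
  p <- length(m$retained)
  expect_equal(
    m$see,
    sqrt(sum((d$vo2max - fitted)^2) / (nrow(d) - p - 1)),
    tolerance = 1e-10
  )
  expect_equal(m$r2, 1 - sum((d$vo2max - fitted)^2) / sum((d$vo2max - mean(d$vo2max))^2))
})

test_that("backward elimination agrees with exhaustive all-significant subsets", {
  # strong two-predictor signal plus junk: the best all-significant subset
  # is unambiguous and backward elimination must find it
  best_subset <- function(d, candidates, alpha = 0.05) {
    subsets <- unlist(
      lapply(0:length(candidates), combn, x = candidates, simplify = FALSE),
      recursive = FALSE
    )
    ok <- list()
    for (s in subsets) {
      fml <- if (length(s) == 0) vo2max ~ 1 else stats::reformulate(s, "vo2max")
      ct <- summary(lm(fml, data = d))$coefficients
      pv <- ct[setdiff(rownames(ct), "(Intercept)"), 4]
      if (length(s) == 0 || all(pv < alpha)) {
        ok[[length(ok) + 1]] <- list(
          set = s, r2 = summary(lm(fml, data = d))$r.squared
        )
      }
    }
    ok[[which.max(vapply(ok, `[[`, numeric(1), "r2"))]]$set
  }
  set.seed(99)
  for (i in 1:10) {
    n <- 40
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), z1 = rnorm(n), z2 = rnorm(n)
    )
    d$vo2max <- 40 + 6 * d$x1 + 5 * d$x2 + rnorm(n, 0, 1)
    m <- backward_stepwise(d, candidates = c("x1", "x2", "z1", "z2"))
    expect_setequal(m$retained, best_subset(d, c("x1", "x2", "z1", "z2")))
  }
})

test_that("degenerate designs and short cohorts are rejected", {
  d <- make_eq_cohort(30, noise_sd = 2, seed = 8)
  d$hrr60_copy <- d$hrr60
  expect_error(
    backward_stepwise(d, candidates = c("hrr60", "hrr60_copy")),
    class = "stepcap_degenerate_design_error"
  )
  expect_error(
    backward_stepwise(d[1:5, ]),
    class = "stepcap_insufficient_data_error"
  )
  expect_error(backward_stepwise(d, alpha = 0), class = "stepcap_validation_error")
})

test_that("CVC classification applies the HRR60 cut-offs as a partition", {
  out <- classify_cvc(tibble::tibble(hrr60 = c(24, 25, 37, 39, 40, 54, 55, 100)))
  expect_equal(
    as.character(out$cvc_class),
    c("Poor", "Moderate", "Moderate", "Moderate", "Good", "Good", "Excellent", "Excellent")
  )
  # every integer recovery maps to exactly one class
  all_int <- classify_cvc(tibble::tibble(hrr60 = 0:120))
  expect_false(any(is.na(all_int$cvc_class)))
  expect_equal(min(all_int$hrr60[all_int$cvc_class == "Moderate"]), 25)
  expect_equal(min(all_int$hrr60[all_int$cvc_class == "Good"]), 40)
  expect_equal(min(all_int$hrr60[all_int$cvc_class == "Excellent"]), 55)
  expect_warning(neg <- classify_cvc(tibble::tibble(hrr60 = -3)), "negative")
  expect_equal(as.character(neg$cvc_class), "Poor")
  bands <- cvc_bands()
  expect_equal(bands$hrr60_min[-1], bands$hrr60_max[-4])
})

test_that("reference VO2max intervals ship both literature columns per sex", {
  ref <- cvc_reference()
  expect_equal(nrow(ref), 16)
  man_exc <- dplyr::filter(ref, sex == "man", cvc_class == "Excellent", source == "study")
  expect_equal(man_exc$vo2max_min, 49)
  woman_poor <- dplyr::filter(ref, sex == "woman", cvc_class == "Poor", source == "study")
  expect_equal(woman_poor$vo2max_max, 28)
  for (s in c("woman", "man")) {
    sub <- cvc_reference(s)
    expect_equal(nrow(sub), 8)
    expect_equal(as.integer(table(sub$source)), c(4L, 4L))
  }
  expect_error(cvc_reference("other"), class = "stepcap_validation_error")
})

test_that("model printing, tidying and serialization round-trip", {
  m <- published_vo2max_model()
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "hrr60"], 0.26)
  gl <- glance(m)
  expect_equal(gl$r.squared, 0.74)
  expect_equal(gl$see, 4.78)
  expect_output(print(m), "17.105")

  d <- make_eq_cohort(40, noise_sd = 3, seed = 13)
  refit <- backward_stepwise(d)
  path <- withr::local_tempfile(fileext = ".txt")
  write_vo2max_model(refit, path)
  back <- read_vo2max_model(path)
  expect_identical(back$coefficients, refit$coefficients)
  expect_identical(back$pvalues, refit$pvalues)
  expect_equal(back$r2, refit$r2)
  expect_equal(back$see, refit$see)
  expect_equal(back$n, refit$n)
  # predictions from the round-tripped model are identical
  expect_identical(
    predict_vo2max(d, back)$vo2max_pred,
    predict_vo2max(d, refit)$vo2max_pred
  )
})
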