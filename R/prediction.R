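# The VO2max prediction equation (published coefficients and backward
# stepwise refits) and HRR60-based cardiovascular-capacity classification.

new_vo2max_model <- function(coefficients, pvalues = NULL, r2 = NA_real_,
                             see = NA_real_, n = NA_integer_, fit = NULL,
                             source = "refit") {
  stopifnot("intercept" %in% names(coefficients))
  structure(
    list(
      coefficients = coefficients,
      retained = setdiff(names(coefficients), "intercept"),
      pvalues = pvalues,
      r2 = r2, see = see, n = n, fit = fit, source = source
    ),
    class = "vo2max_model"
  )
}

#' The published VO2max prediction equation
#'
#' `VO2max = 17.105 + 0.260 x HRR60 + 8.563 x sex + 4.097 x PA_level`,
#' with sex coded 0 for women and 1 for men and PA_level the numeric IPAQ
#' level 1/2/3. Reported fit: R² = 74.0%, SEE = 4.78 mL·kg⁻¹·min⁻¹
#' (derivation cohort n = 30).
#'
#' @return A `vo2max_model` object.
#' @export
#' @examples
#' published_vo2max_model()
published_vo2max_model <- function() {
  new_vo2max_model(
    coefficients = c(intercept = 17.105, hrr60 = 0.260, sex = 8.563, pa_level = 4.097),
    pvalues = c(hrr60 = 0.020, sex = 0.001, pa_level = 0.014),
    r2 = 0.740, see = 4.78, n = 30L, source = "published"
  )
}

#' @export
print.vo2max_model <- function(x, ...) {
  cat(sprintf("VO2max prediction model (%s)\n", x$source))
  rhs <- paste(
    sprintf("%.3f", x$coefficients[["intercept"]]),
    paste(sprintf("%.3f x %s", x$coefficients[x$retained], x$retained),
      collapse = " + "
    ),
    sep = if (length(x$retained) > 0) " + " else ""
  )
  cat("  vo2max =", rhs, "\n")
  if (!is.na(x$r2)) cat(sprintf("  R^2 = %.1f%%, SEE = %.2f, n = %d\n", 100 * x$r2, x$see, x$n))
  invisible(x)
}

#' @export
tidy.vo2max_model <- function(x, ...) {
  terms <- names(x$coefficients)
  tibble(
    term = terms,
    estimate = unname(x$coefficients),
    p.value = unname(x$pvalues[terms])
  )
}

#' @export
glance.vo2max_model <- function(x, ...) {
  tibble(
    r.squared = x$r2, see = x$see, nobs = x$n,
    n_retained = length(x$retained), source = x$source
  )
}

#' Evaluate a VO2max prediction model at given covariates
#'
#' Vectorized evaluation of the linear prediction equation. Values outside
#' the model's fitting domain (sex not in \{0, 1\}, PA level not in
#' \{1, 2, 3\}) are evaluated formally with a warning.
#'
#' @param hrr60 One-minute heart-rate recovery in bpm.
#' @param sex Sex code (0 woman / 1 man) or labels accepted by [sex_code()].
#' @param pa_level Physical-activity level (1 low, 2 moderate, 3 high).
#' @param model A `vo2max_model`; defaults to the published equation. The
#'   model must retain no predictors other than `hrr60`, `sex`, `pa_level`.
#' @return Predicted VO2max in mL·kg⁻¹·min⁻¹.
#' @export
#' @examples
#' vo2max_equation(38, 1, 2)
vo2max_equation <- function(hrr60, sex, pa_level, model = published_vo2max_model()) {
  extra <- setdiff(model$retained, c("hrr60", "sex", "pa_level"))
  if (length(extra) > 0) {
    abort(sprintf(
      "model retains coefficients without supplied covariates: %s",
      paste(extra, collapse = ", ")
    ), class = "stepcap_model_error")
  }
  sx <- if (is.numeric(sex) && any(!sex %in% c(0, 1), na.rm = TRUE)) {
    warn("sex code outside {0, 1}: formal evaluation")
    sex
  } else {
    sex_code(sex)
  }
  if (any(!pa_level %in% 1:3, na.rm = TRUE)) {
    warn("pa_level outside {1, 2, 3}: formal evaluation")
  }
  co <- model$coefficients
  co_of <- function(term) if (term %in% names(co)) co[[term]] else 0
  co[["intercept"]] + co_of("hrr60") * hrr60 + co_of("sex") * sx +
    co_of("pa_level") * pa_level
}

#' Predict VO2max for a cohort
#'
#' Evaluates a prediction model row-wise over a cohort data frame. The data
#' must contain one column per retained model coefficient (for the published
#' equation: `hrr60`, `sex`, `pa_level`).
#'
#' @param data Cohort data frame.
#' @param model A `vo2max_model` (default: the published equation).
#' @return The input tibble with `vo2max_pred` appended.
#' @export
#' @examples
#' library(tibble)
#' predict_vo2max(tibble(hrr60 = 38, sex = "man", pa_level = 2))
predict_vo2max <- function(data, model = published_vo2max_model()) {
  missing <- setdiff(model$retained, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "data lacks column(s) for model coefficient(s): %s",
      paste(missing, collapse = ", ")
    ), class = "stepcap_model_error")
  }
  d <- as_tibble(data)
  co <- model$coefficients
  pred <- rep(co[["intercept"]], nrow(d))
  for (term in model$retained) {
    x <- d[[term]]
    if (term == "sex") x <- sex_code(x)
    pred <- pred + co[[term]] * x
  }
  if ("pa_level" %in% model$retained && any(!d$pa_level %in% 1:3, na.rm = TRUE)) {
    warn("pa_level outside {1, 2, 3}: formal evaluation")
  }
  d |> mutate(vo2max_pred = pred)
}

#' Refit the prediction equation by backward elimination
#'
#' Starts from the full ordinary-least-squares model on all candidate
#' predictors and repeatedly removes the predictor with the largest p-value
#' at or above `alpha`, refitting until every retained predictor is
#' significant. Reports coefficients, per-predictor p-values, R² and the
#' standard error of the estimate (residual standard error, n - p - 1
#' denominator).
#'
#' @param data Cohort data frame containing `outcome` and all candidate
#'   columns; a `sex` column may hold labels, which are recoded 0/1.
#' @param outcome Name of the outcome column (default `"vo2max"`).
#' @param candidates Candidate predictor columns. Default mirrors the
#'   method's candidate set; add `"age"` to test its contribution.
#' @param alpha Retention threshold on p-values (default 0.05).
#' @return A `vo2max_model` with the retained coefficients.
#' @export
backward_stepwise <- function(data,
                              outcome = "vo2max",
                              candidates = c(
                                "sex", "body_mass", "height", "bmi",
                                "pa_level", "hrr60"
                              ),
                              alpha = 0.05) {
  check_columns(data, c(outcome, candidates), "cohort data")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")
  d <- as_tibble(data)[, c(outcome, candidates)]
  if ("sex" %in% candidates) d$sex <- sex_code(d$sex)
  d <- d[complete.cases(d), ]
  if (nrow(d) < length(candidates) + 2) {
    stop_insufficient(sprintf(
      "need at least %d complete records, got %d",
      length(candidates) + 2, nrow(d)
    ))
  }

  kept <- candidates
  repeat {
    fml <- if (length(kept) > 0) {
      stats::reformulate(kept, response = outcome)
    } else {
      stats::reformulate("1", response = outcome)
    }
    fit <- lm(fml, data = d)
    if (any(is.na(coef(fit)))) {
      abort(sprintf(
        "degenerate design: aliased column(s) %s",
        paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
      ), class = "stepcap_degenerate_design_error")
    }
    if (length(kept) == 0) break
    ct <- summary(fit)$coefficients
    p <- ct[setdiff(rownames(ct), "(Intercept)"), "Pr(>|t|)", drop = TRUE]
    names(p) <- setdiff(rownames(ct), "(Intercept)")
    if (max(p) < alpha) break
    kept <- setdiff(kept, names(which.max(p)))
  }

  s <- summary(fit)
  co <- coef(fit)
  names(co)[names(co) == "(Intercept)"] <- "intercept"
  pv <- if (length(kept) > 0) {
    ct <- s$coefficients
    stats::setNames(
      ct[kept, "Pr(>|t|)"],
      kept
    )
  } else {
    numeric(0)
  }
  new_vo2max_model(
    coefficients = co, pvalues = pv,
    r2 = s$r.squared, see = s$sigma, n = nrow(d), fit = fit,
    source = "refit"
  )
}

# CVC classification ----------------------------------------------------------

cvc_levels <- c("Poor", "Moderate", "Good", "Excellent")

#' HRR60 bands of the cardiovascular-capacity classification
#'
#' Poor \[0, 25), Moderate \[25, 40), Good \[40, 55), Excellent \[55, Inf).
#' Half-open bands guarantee that every non-negative recovery maps to
#' exactly one class.
#'
#' @return Tibble with columns `cvc_class`, `hrr60_min`, `hrr60_max`.
#' @export
#' @examples
#' cvc_bands()
cvc_bands <- function() {
  tibble(
    cvc_class = factor(cvc_levels, levels = cvc_levels, ordered = TRUE),
    hrr60_min = c(0, 25, 40, 55),
    hrr60_max = c(25, 40, 55, Inf)
  )
}

#' Classify cardiovascular capacity from HRR60
#'
#' Applies the HRR60 cut-offs (< 25 poor, 25--39 moderate, 40--54 good,
#' >= 55 excellent) to a cohort. Negative recoveries are flagged and
#' classified Poor.
#'
#' @param data Data frame with an `hrr60` column (bpm).
#' @return The input tibble with `cvc_class` (ordered factor) appended.
#' @export
#' @examples
#' library(tibble)
#' classify_cvc(tibble(hrr60 = c(12, 37, 48, 60)))
classify_cvc <- function(data) {
  check_columns(data, "hrr60", "data")
  d <- as_tibble(data)
  if (any(d$hrr60 < 0, na.rm = TRUE)) {
    warn("negative hrr60 value(s) classified as Poor")
  }
  cls <- cut(pmax(d$hrr60, 0),
    breaks = c(-Inf, 25, 40, 55, Inf),
    labels = cvc_levels, right = FALSE, ordered_result = TRUE
  )
  d |> mutate(cvc_class = cls)
}

#' Reference VO2max intervals per cardiovascular-capacity class
#'
#' Sex-specific VO2max reference intervals (mL·kg⁻¹·min⁻¹) associated with
#' the HRR60 classes, for young adults: the study-derived columns and the
#' comparable McArdle et al. normative columns. These are untransformed
#' literature values shipped for reporting only; classification always keys
#' on HRR60 ([classify_cvc()]), never on these intervals (which, as
#' printed, contain gaps).
#'
#' @param sex Optional filter: `"woman"` or `"man"`.
#' @return Tibble with columns `sex`, `cvc_class`, `source` (`"study"` or
#'   `"mcardle"`), `vo2max_min`, `vo2max_max` (open bounds as -Inf/Inf).
#' @export
#' @examples
#' cvc_reference("man")
cvc_reference <- function(sex = NULL) {
  cls <- factor(cvc_levels, levels = cvc_levels, ordered = TRUE)
  ref <- bind_rows(
    tibble(
      sex = "man", cvc_class = cls, source = "study",
      vo2max_min = c(-Inf, 42, 44.3, 49),
      vo2max_max = c(40, 44.2, 49, Inf)
    ),
    tibble(
      sex = "man", cvc_class = cls, source = "mcardle",
      vo2max_min = c(-Inf, 36.5, 42.5, 46.5),
      vo2max_max = c(36.5, 42.4, 46.4, Inf)
    ),
    tibble(
      sex = "woman", cvc_class = cls, source = "study",
      vo2max_min = c(-Inf, 28, 32.3, 37),
      vo2max_max = c(28, 32.2, 36.9, Inf)
    ),
    tibble(
      sex = "woman", cvc_class = cls, source = "mcardle",
      vo2max_min = c(-Inf, 29, 33, 37),
      vo2max_max = c(29, 32, 36, Inf)
    )
  )
  if (!is.null(sex)) {
    if (!sex %in% c("woman", "man")) stop_validation("sex must be 'woman' or 'man'")
    ref <- ref |> filter(.data$sex == !!sex)
  }
  ref
}
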