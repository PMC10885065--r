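# IPAQ short-form scoring: weekly MET-minutes and the three-level
# physical-activity classification used as a predictor of VO2max.

#' MET weights for the IPAQ short form
#'
#' The short-form scoring protocol assigns one MET intensity per activity
#' category: walking 3.3, moderate activity 4.0, vigorous activity 8.0.
#' Override individual weights to explore sensitivity.
#'
#' @param walking,moderate,vigorous MET weight per category.
#' @return Named numeric vector of MET weights.
#' @export
#' @examples
#' ipaq_met_weights()
ipaq_met_weights <- function(walking = 3.3, moderate = 4.0, vigorous = 8.0) {
  w <- c(walking = walking, moderate = moderate, vigorous = vigorous)
  if (any(w < 0)) stop_validation("MET weights must be non-negative")
  w
}

ipaq_cols <- c(
  "vigorous_days", "vigorous_min",
  "moderate_days", "moderate_min",
  "walking_days", "walking_min"
)

validate_ipaq <- function(data) {
  check_columns(data, ipaq_cols, "IPAQ response data")
  days <- c("vigorous_days", "moderate_days", "walking_days")
  mins <- c("vigorous_min", "moderate_min", "walking_min")
  for (col in days) {
    x <- data[[col]]
    if (any(x < 0 | x > 7, na.rm = TRUE)) {
      stop_validation(sprintf("%s must lie in [0, 7] days/week", col))
    }
  }
  for (col in mins) {
    if (any(data[[col]] < 0, na.rm = TRUE)) {
      stop_validation(sprintf("%s must be non-negative", col))
    }
  }
  invisible(data)
}

#' Score IPAQ short-form responses
#'
#' Converts per-category days/week and minutes/day into weekly MET-minutes
#' (category value = days x minutes x MET weight) and classifies each
#' respondent into the three-level physical-activity scheme:
#'
#' * **High (3)**: at least 3 days of vigorous activity with a total energy
#'   expenditure of at least 1500 MET-min/week; or activity on 7 or more
#'   day-counts summed across categories with a total of at least
#'   3000 MET-min/week.
#' * **Moderate (2)**: at least 3 days of vigorous activity of at least
#'   20 min/day; or 5 or more days (summed over categories reporting at least
#'   30 min/day) of walking, moderate or vigorous activity; or activity on 5
#'   or more summed day-counts with a total of at least 600 MET-min/week.
#' * **Low (1)**: anything else.
#'
#' The 1500 MET-min threshold of the first High clause is interpreted as
#' *total* weekly MET-minutes (the official-protocol reading); the 7-day
#' clause counts any combination of categories unless
#' `high_requires_all_categories = TRUE`, which additionally requires a
#' nonzero day count in each of walking, moderate and vigorous activity.
#'
#' @param data Data frame with columns `vigorous_days`, `vigorous_min`,
#'   `moderate_days`, `moderate_min`, `walking_days`, `walking_min`
#'   (days/week in \[0, 7\], minutes/day >= 0). Other columns pass through.
#' @param weights MET weights, see [ipaq_met_weights()].
#' @param truncate_minutes Optional per-day minute cap applied before scoring
#'   (the official cleaning protocol uses 180); `NULL` (default) applies no
#'   truncation.
#' @param high_requires_all_categories Stricter reading of the 7-day High
#'   clause, see above.
#' @return The input tibble with `met_min_walking`, `met_min_moderate`,
#'   `met_min_vigorous`, `met_min_total`, `pa_level` (integer 1/2/3) and
#'   `pa_label` (ordered factor Low/Moderate/High) appended.
#' @export
#' @examples
#' library(tibble)
#' ipaq_score(tibble(
#'   vigorous_days = 3, vigorous_min = 25,
#'   moderate_days = 0, moderate_min = 0,
#'   walking_days = 0, walking_min = 0
#' ))
ipaq_score <- function(data, weights = ipaq_met_weights(),
                       truncate_minutes = NULL,
                       high_requires_all_categories = FALSE) {
  validate_ipaq(data)
  d <- as_tibble(data)

  cap <- function(x) if (is.null(truncate_minutes)) x else pmin(x, truncate_minutes)
  vig_min <- cap(d$vigorous_min)
  mod_min <- cap(d$moderate_min)
  walk_min <- cap(d$walking_min)

  met_vig <- d$vigorous_days * vig_min * weights[["vigorous"]]
  met_mod <- d$moderate_days * mod_min * weights[["moderate"]]
  met_walk <- d$walking_days * walk_min * weights[["walking"]]
  total <- met_vig + met_mod + met_walk

  sum_days <- d$vigorous_days + d$moderate_days + d$walking_days
  # day counts from categories reporting >= 30 min/day
  days_30 <- d$vigorous_days * (vig_min >= 30) +
    d$moderate_days * (mod_min >= 30) +
    d$walking_days * (walk_min >= 30)

  all_categories <- d$vigorous_days > 0 & d$moderate_days > 0 & d$walking_days > 0
  seven_day_ok <- if (high_requires_all_categories) {
    sum_days >= 7 & all_categories
  } else {
    sum_days >= 7
  }

  high <- (d$vigorous_days >= 3 & total >= 1500) |
    (seven_day_ok & total >= 3000)
  moderate <- (d$vigorous_days >= 3 & vig_min >= 20) |
    (days_30 >= 5) |
    (sum_days >= 5 & total >= 600)

  level <- dplyr::if_else(high, 3L, dplyr::if_else(moderate, 2L, 1L))

  d |>
    mutate(
      met_min_walking = met_walk,
      met_min_moderate = met_mod,
      met_min_vigorous = met_vig,
      met_min_total = total,
      pa_level = level,
      pa_label = pa_label_of(level)
    )
}

#' Map physical-activity level codes to labels (and back)
#'
#' @param level Integer vector with values in \{1, 2, 3\}.
#' @return `pa_label_of()`: ordered factor with levels Low < Moderate < High.
#' @export
#' @examples
#' pa_label_of(1:3)
pa_label_of <- function(level) {
  if (any(!level %in% 1:3, na.rm = TRUE)) {
    stop_validation("pa_level must be 1 (Low), 2 (Moderate) or 3 (High)")
  }
  factor(c("Low", "Moderate", "High")[level],
    levels = c("Low", "Moderate", "High"), ordered = TRUE
  )
}
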