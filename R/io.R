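# File interfaces: session time-series CSVs, cohort CSVs, model
# serialization and report export. Comma-separated, UTF-8, header row,
# "." decimal separator throughout.

session_col_types <- readr::cols(
  time_s = readr::col_double(),
  hr_bpm = readr::col_double(),
  vo2_mlkgmin = readr::col_double(),
  phase = readr::col_character()
)

#' Read a session time-series CSV
#'
#' Expected columns: `time_s`, `hr_bpm`, `vo2_mlkgmin` (may be blank during
#' recovery), `phase` (`rest`, `stage_1` ... `stage_10`, `recovery`).
#' Malformed content is reported with data line numbers.
#'
#' @param path Path to the CSV file.
#' @return Validated session tibble.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  d <- suppressWarnings(
    readr::read_csv(path, col_types = session_col_types, progress = FALSE)
  )
  check_columns(d, session_cols, basename(path))
  pb <- readr::problems(d)
  if (nrow(pb) > 0) {
    stop_validation(sprintf(
      "malformed content at data line(s) %s of %s",
      paste(head(unique(pb$row), 5), collapse = ", "), basename(path)
    ))
  }
  bad_phase <- which(!grepl("^(rest|recovery|stage_[0-9]+)$", d$phase))
  if (length(bad_phase) > 0) {
    stop_validation(sprintf(
      "unknown phase label(s) at data line(s) %s of %s",
      paste(head(bad_phase, 5), collapse = ", "), basename(path)
    ))
  }
  non_mono <- which(diff(d$time_s) <= 0)
  if (length(non_mono) > 0) {
    stop_validation(sprintf(
      "time_s not strictly increasing at data line(s) %s of %s",
      paste(head(non_mono + 1, 5), collapse = ", "), basename(path)
    ))
  }
  bad_hr <- which(!is.finite(d$hr_bpm) | d$hr_bpm <= 0)
  if (length(bad_hr) > 0) {
    stop_validation(sprintf(
      "invalid hr_bpm at data line(s) %s of %s",
      paste(head(bad_hr, 5), collapse = ", "), basename(path)
    ))
  }
  validate_session(d)
  d
}

#' Write a session time-series CSV
#'
#' @param session Session tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_session_csv <- function(session, path) {
  validate_session(session)
  readr::write_csv(session, path, progress = FALSE)
  invisible(path)
}

#' Serialize a VO2max prediction model to a plain-text file
#'
#' Key-value format (`key value` per line, full double precision), holding
#' the coefficients, per-predictor p-values and fit summaries. The file is
#' round-trippable with [read_vo2max_model()].
#'
#' @param model A `vo2max_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vo2max_model <- function(model, path) {
  if (!inherits(model, "vo2max_model")) stop_validation("model must be a vo2max_model")
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste("source", model$source),
    paste("n", model$n),
    paste("r2", num(model$r2)),
    paste("see", num(model$see)),
    paste("coef.intercept", num(model$coefficients[["intercept"]])),
    vapply(model$retained, function(t) {
      paste(paste0("coef.", t), num(model$coefficients[[t]]))
    }, character(1)),
    vapply(names(model$pvalues %||% numeric(0)), function(t) {
      paste(paste0("p.", t), num(model$pvalues[[t]]))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a VO2max prediction model from a plain-text file
#'
#' @param path Path written by [write_vo2max_model()].
#' @return A `vo2max_model`.
#' @export
read_vo2max_model <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, " +")
  keys <- vapply(parts, `[[`, character(1), 1)
  vals <- vapply(parts, `[[`, character(1), 2)
  kv <- setNames(vals, keys)
  coef_keys <- grep("^coef\\.", keys, value = TRUE)
  co <- setNames(
    as.numeric(kv[coef_keys]),
    sub("^coef\\.", "", coef_keys)
  )
  p_keys <- grep("^p\\.", keys, value = TRUE)
  pv <- setNames(as.numeric(kv[p_keys]), sub("^p\\.", "", p_keys))
  new_vo2max_model(
    coefficients = co, pvalues = pv,
    r2 = as.numeric(kv[["r2"]]), see = as.numeric(kv[["see"]]),
    n = as.integer(kv[["n"]]), source = kv[["source"]]
  )
}

#' Write a tidy report to JSON or CSV
#'
#' Serializes the [tidy()] representation of a fitted object (agreement
#' report or prediction model) at full numeric precision, so that a
#' read-back with [read_report()] reproduces the written values exactly.
#'
#' @param x An `agreement_report`, `vo2max_model`, or a tidy data frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; default inferred from the file
#'   extension.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  td <- if (is.data.frame(x)) as_tibble(x) else tidy(x)
  if (format == "json") {
    jsonlite::write_json(td, path, digits = NA, na = "null")
  } else {
    readr::write_csv(td, path, progress = FALSE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path (.json or .csv).
#' @return Tibble with the report's tidy rows.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
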