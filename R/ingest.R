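# CSV ingest: read, validate and normalize the four input tables.
#
# Dialect: comma-separated, UTF-8, header row required, ISO-8601 dates, day
# precision throughout (times of day are discarded: every downstream
# statistic is day-granular). Two validation modes: "lenient" drops malformed
# rows and counts them in the validation report; "strict" fails on the first
# problem. "paper"-strictness date-window checks flag records outside the
# study's collection windows (HbA1c 2014-01 .. 2018-11, account creation
# 2015-12 .. 2018-04) without dropping them.

read_table_checked <- function(path, col_types, required, mode) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "phr_io_error")
  }
  # malformed cells are counted by our own validation below; silence the
  # reader's per-cell parse chatter
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "phr_schema_error")
  }
  raw
}

finish_validation <- function(data, bad, mode, what) {
  n_bad <- sum(bad)
  if (n_bad > 0 && mode == "strict") {
    abort(sprintf("%d malformed %s row(s) in strict mode.", n_bad, what),
          class = "phr_validation_error")
  }
  list(data = data[!bad, , drop = FALSE],
       report = list(table = what, n_read = nrow(data),
                     n_kept = nrow(data) - n_bad, n_dropped = n_bad))
}

#' Read the app-usage log
#'
#' One row per data-entry event: `user_id`, `function`, `event_date`.
#' Function names other than `sugar` / `diabetes_calendar` are retained but
#' mapped to `other` (the analysis only uses the first two). Rows with an
#' unparseable date or empty user id are malformed.
#'
#' @param path CSV file.
#' @param mode `"lenient"` (drop and count malformed rows) or `"strict"`
#'   (fail on them).
#' @return `list(data = <tibble of log events>, report = <validation counts>)`.
#' @export
read_log <- function(path, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  raw <- read_table_checked(
    path,
    readr::cols(user_id = readr::col_character(),
                `function` = readr::col_character(),
                event_date = readr::col_date(format = "")),
    c("user_id", "function", "event_date"), mode)
  bad <- is.na(raw$event_date) | is.na(raw$user_id) | raw$user_id == ""
  raw$`function` <- ifelse(
    raw$`function` %in% c("sugar", "diabetes_calendar"),
    raw$`function`, "other")
  finish_validation(raw, bad, mode, "log")
}

#' Read the HbA1c laboratory extract
#'
#' Columns `user_id`, `measure_date`, `value` (%). Values outside the hard
#' assay validity bounds 3--20% are malformed (a "65" is an mmol/mol or
#' transcription artefact, never a percentage).
#'
#' @inheritParams read_log
#' @param window_check flag dates outside the study collection window
#'   (2014-01-01 .. 2018-11-30) in the report (records are kept).
#' @return `list(data, report)`; the report counts out-of-window dates.
#' @export
read_hba1c <- function(path, mode = c("lenient", "strict"),
                       window_check = TRUE) {
  mode <- match.arg(mode)
  raw <- read_table_checked(
    path,
    readr::cols(user_id = readr::col_character(),
                measure_date = readr::col_date(format = ""),
                value = readr::col_double()),
    c("user_id", "measure_date", "value"), mode)
  bad <- is.na(raw$measure_date) | is.na(raw$user_id) | raw$user_id == "" |
    is.na(raw$value) | raw$value < 3 | raw$value > 20
  out <- finish_validation(raw, bad, mode, "hba1c")
  if (window_check) {
    d <- out$data$measure_date
    out$report$n_outside_window <-
      sum(d < .study_windows$hba1c_min | d > .study_windows$hba1c_max)
  }
  dup <- duplicated(out$data[, c("user_id", "measure_date")])
  out$report$n_same_day_duplicates <- sum(dup)
  out
}

#' Read the diagnosis extract
#'
#' Columns `user_id`, `icd10_code`, `diagnosis_date`. Codes are normalized
#' (uppercased, dot stripped): `E11.9` and `E119` are the same diagnosis.
#' Codes that do not match the ICD-10 lexical pattern are malformed.
#'
#' @inheritParams read_log
#' @return `list(data, report)`; `icd10_code` holds the normalized code.
#' @export
read_diagnoses <- function(path, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  raw <- read_table_checked(
    path,
    readr::cols(user_id = readr::col_character(),
                icd10_code = readr::col_character(),
                diagnosis_date = readr::col_date(format = "")),
    c("user_id", "icd10_code", "diagnosis_date"), mode)
  norm <- normalize_icd10(raw$icd10_code)
  bad <- is.na(norm) | is.na(raw$user_id) | raw$user_id == "" |
    is.na(raw$diagnosis_date)
  raw$icd10_code <- norm
  finish_validation(raw, bad, mode, "diagnoses")
}

#' Read the user demographics table
#'
#' Columns `user_id`, `account_creation_date`, `age`, `sex`
#' (`male`/`female`). Negative ages and unknown sex levels are malformed.
#'
#' @inheritParams read_log
#' @param window_check flag creation dates outside the app's operating window
#'   (2015-12-01 .. 2018-04-30) in the report (records are kept).
#' @return `list(data, report)`.
#' @export
read_users <- function(path, mode = c("lenient", "strict"),
                       window_check = TRUE) {
  mode <- match.arg(mode)
  raw <- read_table_checked(
    path,
    readr::cols(user_id = readr::col_character(),
                account_creation_date = readr::col_date(format = ""),
                age = readr::col_double(),
                sex = readr::col_character()),
    c("user_id", "account_creation_date", "age", "sex"), mode)
  bad <- is.na(raw$account_creation_date) | is.na(raw$user_id) |
    raw$user_id == "" | is.na(raw$age) | raw$age < 0 |
    !(raw$sex %in% c("male", "female"))
  out <- finish_validation(raw, bad, mode, "users")
  if (window_check) {
    d <- out$data$account_creation_date
    out$report$n_outside_window <-
      sum(d < .study_windows$creation_min | d > .study_windows$creation_max)
  }
  if (anyDuplicated(out$data$user_id)) {
    abort("duplicate user_id in users table.", class = "phr_validation_error")
  }
  out
}

#' Keep only app events on or after account creation
#'
#' Events logged before a user's account-creation day are artefacts of the
#' platform migration and are removed. At day precision "after account
#' creation" is read as on-or-after the creation day. Idempotent; never
#' increases the event count.
#'
#' @param events tibble of log events (`user_id`, `function`, `event_date`).
#' @param users tibble with `user_id`, `account_creation_date`.
#' @param unknown_user `"drop"` (default: drop events for users missing from
#'   `users`, with a warning) or `"fail"`.
#' @return `list(data = filtered events, report = counts removed)`.
#' @export
filter_post_creation <- function(events, users,
                                 unknown_user = c("drop", "fail")) {
  unknown_user <- match.arg(unknown_user)
  joined <- dplyr::left_join(
    events, dplyr::select(users, "user_id", "account_creation_date"),
    by = "user_id")
  unknown <- is.na(joined$account_creation_date)
  if (any(unknown)) {
    if (unknown_user == "fail") {
      abort(sprintf("%d event(s) reference unknown users.", sum(unknown)),
            class = "phr_validation_error")
    }
    warn(sprintf("dropping %d event(s) for unknown users.", sum(unknown)))
  }
  pre <- !unknown & joined$event_date < joined$account_creation_date
  keep <- !unknown & !pre
  list(data = events[keep, , drop = FALSE],
       report = list(n_in = nrow(events), n_kept = sum(keep),
                     n_pre_creation = sum(pre),
                     n_unknown_user = sum(unknown)))
}
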