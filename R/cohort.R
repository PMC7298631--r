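# Cohort construction: inclusion/exclusion flow and continuous-use
# classification.
#
# Inclusion requires an "appropriate" HbA1c measurement history (>= 2 results
# spanning strictly more than 100 days, with account creation inside the
# span: short spans make trend slopes meaninglessly steep) and a diabetes
# diagnosis (any ICD-10 code with root E08/E09/E10/E11/E13, or first HbA1c
# >= 6.5%, the KDA target threshold). Included users are then split by the
# continuous-use rule on their blood-glucose diary events.

diabetes_roots <- c("E08", "E09", "E10", "E11", "E13")

#' Is a user's HbA1c measurement history appropriate for trend analysis?
#'
#' True iff the user has at least two measurements, the first-to-last span is
#' strictly over 100 days, and the account was created during the measurement
#' span (first date <= creation <= last date).
#'
#' @param measure_dates the user's HbA1c measurement dates.
#' @param creation_date the user's account-creation date.
#' @return logical flag.
#' @export
is_appropriate_measurement <- function(measure_dates, creation_date) {
  if (length(measure_dates) < 2) return(FALSE)
  first <- min(measure_dates)
  last <- max(measure_dates)
  as.numeric(last - first) > 100 &&
    creation_date >= first && creation_date <= last
}

#' Does a user meet the diabetes criteria?
#'
#' True iff any diagnosis code has a 3-character root in
#' E08/E09/E10/E11/E13 (codes are matched on the root, so E11.9 counts), or
#' the first HbA1c measurement is at or above the 6.5% diagnostic cutoff.
#'
#' @param codes the user's ICD-10 diagnosis codes (any, possibly empty).
#' @param first_hba1c the user's chronologically first HbA1c value, %.
#' @return logical flag.
#' @export
is_diabetic <- function(codes, first_hba1c) {
  codes <- normalize_icd10(codes)
  codes <- codes[!is.na(codes)]
  (length(codes) > 0 && any(substr(codes, 1, 3) %in% diabetes_roots)) ||
    (is.finite(first_hba1c) && first_hba1c >= 6.5)
}

#' Classify continuous app use from blood-glucose diary events
#'
#' The rule: data entered at least once per week, sustained for at least four
#' weeks (28 days). Under the default `"anchored_bins"` interpretation, days
#' are binned into consecutive 7-day bins anchored at the user's first sugar
#' event, and the user is continuous iff some run of >= 4 consecutive bins
#' are all non-empty. Alternatives: `"calendar_weeks"` (ISO Monday-anchored
#' weeks) and `"window28"` (some 28-day window whose four 7-day bins are all
#' non-empty; the only interpretation that is monotone under adding events).
#' Duplicate same-day events and event order never matter.
#'
#' @param event_dates dates of the user's post-creation sugar events.
#' @param rule which reading of the weekly rule to apply.
#' @return logical flag (`FALSE` for fewer than 4 events).
#' @export
classify_continuous <- function(event_dates,
                                rule = c("anchored_bins", "calendar_weeks",
                                         "window28")) {
  rule <- match.arg(rule)
  if (length(event_dates) == 0) return(FALSE)
  days <- sort(unique(as.integer(as.Date(event_dates))))
  if (length(days) < 4) return(FALSE)
  longest_run <- function(bins) {
    bins <- sort(unique(bins))
    if (length(bins) == 0) return(0L)
    max(tabulate(cumsum(c(1L, diff(bins) != 1L))))
  }
  switch(rule,
    anchored_bins = longest_run((days - days[1]) %/% 7L) >= 4L,
    calendar_weeks = {
      # 1970-01-05 was a Monday; bin by ISO-style Monday weeks
      longest_run((days - 4L) %/% 7L) >= 4L
    },
    window28 = {
      any(vapply(days, function(t0) {
        d <- days[days >= t0 & days <= t0 + 27L]
        length(unique((d - t0) %/% 7L)) == 4L
      }, logical(1)))
    })
}

#' Build the study cohort and the inclusion/exclusion flow
#'
#' Applies, per user: the appropriate-measurement filter, the diabetes
#' criteria, and (for included users) the continuous-use classification of
#' their post-creation sugar events. The flow counts satisfy the exact
#' identities `n_accounts = n_inappropriate + n_appropriate`,
#' `n_appropriate = n_no_diabetes + n_diabetes` and
#' `n_diabetes = n_continuous + n_noncontinuous` on every input.
#'
#' @param users validated demographics tibble.
#' @param log_events validated, post-creation-filtered log events.
#' @param hba1c validated HbA1c measurements.
#' @param diagnoses validated diagnosis records.
#' @param rule passed to [classify_continuous()].
#' @param unknown_user `"drop"` (ignore lab/diagnosis/log rows whose user is
#'   absent from `users`) or `"fail"`.
#' @return `list(cohort = <per-user tibble>, flow = <flow counts>)`. The
#'   cohort tibble has one row per account with flags
#'   `appropriate_measurement`, `diabetic`, `continuous_user` (NA for
#'   excluded users), `exclusion_reason`, and the per-user measurement
#'   summaries `n_hba1c`, `span_days`, `first_hba1c`, `last_hba1c`.
#' @export
build_cohort <- function(users, log_events, hba1c, diagnoses,
                         rule = c("anchored_bins", "calendar_weeks",
                                  "window28"),
                         unknown_user = c("drop", "fail")) {
  rule <- match.arg(rule)
  unknown_user <- match.arg(unknown_user)
  for (tbl in list(hba1c, diagnoses, log_events)) {
    stray <- setdiff(unique(tbl$user_id), users$user_id)
    if (length(stray) > 0 && unknown_user == "fail") {
      abort(sprintf("%d user id(s) absent from the users table.",
                    length(stray)), class = "phr_validation_error")
    }
  }
  hb_by_user <- split(hba1c[, c("measure_date", "value")], hba1c$user_id)
  dx_by_user <- split(diagnoses$icd10_code, diagnoses$user_id)
  sugar <- log_events[log_events$`function` == "sugar", , drop = FALSE]
  sugar_by_user <- split(sugar$event_date, sugar$user_id)

  n <- nrow(users)
  appropriate <- logical(n); diabetic <- logical(n)
  continuous <- rep(NA, n)
  n_hba1c <- integer(n); span_days <- numeric(n)
  first_v <- rep(NA_real_, n); last_v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    uid <- users$user_id[i]
    creation <- users$account_creation_date[i]
    hb <- hb_by_user[[uid]]
    if (!is.null(hb)) hb <- hb[order(hb$measure_date), , drop = FALSE]
    n_hb <- if (is.null(hb)) 0L else nrow(hb)
    n_hba1c[i] <- n_hb
    if (n_hb > 0) {
      first_v[i] <- hb$value[1]
      last_v[i] <- hb$value[n_hb]
      span_days[i] <- if (n_hb > 1) {
        as.numeric(hb$measure_date[n_hb] - hb$measure_date[1])
      } else 0
      appropriate[i] <- is_appropriate_measurement(hb$measure_date, creation)
    }
    diabetic[i] <- appropriate[i] &&
      is_diabetic(dx_by_user[[uid]] %||% character(), first_v[i])
    if (appropriate[i] && diabetic[i]) {
      continuous[i] <- classify_continuous(
        sugar_by_user[[uid]] %||% as.Date(character()), rule = rule)
    }
  }
  cohort <- tibble::tibble(
    user_id = as.character(users$user_id),
    appropriate_measurement = appropriate,
    diabetic = diabetic,
    continuous_user = as.logical(continuous),
    exclusion_reason = ifelse(!appropriate, "inappropriate_measurement",
                              ifelse(!diabetic, "no_diabetes", "none")),
    n_hba1c = n_hba1c, span_days = span_days,
    first_hba1c = first_v, last_hba1c = last_v)
  flow <- flow_counts(cohort)
  list(cohort = cohort, flow = flow)
}

#' Flow counts for a cohort table
#'
#' @param cohort the per-user tibble from [build_cohort()].
#' @return named list mirroring the inclusion-flow boxes.
#' @export
flow_counts <- function(cohort) {
  n_accounts <- nrow(cohort)
  n_appropriate <- sum(cohort$appropriate_measurement)
  n_diabetes <- sum(cohort$diabetic)
  n_continuous <- sum(cohort$continuous_user %in% TRUE)
  list(
    n_accounts = n_accounts,
    n_inappropriate = n_accounts - n_appropriate,
    n_appropriate = n_appropriate,
    n_no_diabetes = n_appropriate - n_diabetes,
    n_diabetes = n_diabetes,
    n_continuous = n_continuous,
    n_noncontinuous = n_diabetes - n_continuous
  )
}
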