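# Per-patient HbA1c trajectory statistics.
#
# The core quantity is the span-normalised trend statistic "decline": the
# ordinary-least-squares trend-line slope (%/day) times the first-to-last
# span in days, divided by 100. Algebraically, 100 * decline equals the
# change in the fitted HbA1c value between the first and last measurement
# dates, so a decline of -0.0044 means the fitted HbA1c fell by about 0.44
# percentage points over the patient's whole span. The abscissa is days
# since the first measurement, which makes every statistic invariant to
# shifting all dates by a constant.

#' Ordinary least-squares trend of HbA1c on time
#'
#' Fits `value ~ days-since-first-measurement` by closed-form OLS.
#' `r_squared = 1 - SSresid/SStot`, defined as 1 when the fit is exact:
#' with n = 2 points, or when all values are equal (SStot = 0).
#'
#' @param days numeric days (any origin; internally re-centred on the first).
#' @param values HbA1c values, %.
#' @return `list(slope = %/day, intercept = % at the first measurement date,
#'   r_squared)`.
#' @export
fit_trend <- function(days, values) {
  n <- length(days)
  if (n < 2 || length(values) != n) {
    abort("need at least two (day, value) pairs.", class = "phr_argument_error")
  }
  x <- as.numeric(days) - min(as.numeric(days))
  if (all(x == x[1])) {
    abort("all measurement dates identical: trend undefined.",
          class = "phr_degenerate_error")
  }
  y <- as.numeric(values)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  sstot <- sum((y - yb)^2)
  ssres <- sstot - slope * sxy
  r2 <- if (sstot <= 0 || n == 2) 1 else max(0, min(1, 1 - ssres / sstot))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' The span-normalised decline statistic
#'
#' `decline = slope * span_days / 100`. Equivalently (identically, by OLS
#' algebra) the fitted HbA1c change from the first to the last measurement
#' date divided by 100.
#'
#' @param slope OLS trend slope, %/day.
#' @param span_days days between first and last measurement (> 0).
#' @return unitless decline.
#' @export
compute_decline <- function(slope, span_days) {
  if (any(span_days <= 0)) {
    abort("`span_days` must be > 0.", class = "phr_argument_error")
  }
  slope * span_days / 100
}

#' Dispersion summaries of a measurement series
#'
#' @param values HbA1c values in chronological order (>= 2).
#' @return `list(sd = sample SD (n-1 denominator), first_value, last_value)`.
#' @export
compute_dispersion <- function(values) {
  if (length(values) < 2) {
    abort("need at least two values.", class = "phr_argument_error")
  }
  list(sd = sd(values), first_value = values[1],
       last_value = values[length(values)])
}

#' Glycemic regulation class from first and last HbA1c
#'
#' Classifies the (first, last) pair against the 6.5% target: `high` means
#' at or above the threshold (inclusive on the high side), `low` below it.
#'
#' @param first_value,last_value HbA1c, %.
#' @param threshold target threshold, % (default the KDA 6.5%).
#' @return one of `"low_low"`, `"low_high"`, `"high_low"`, `"high_high"`
#'   (first component = first measurement).
#' @export
classify_regulation <- function(first_value, last_value, threshold = 6.5) {
  lab <- function(v) ifelse(v >= threshold, "high", "low")
  paste(lab(first_value), lab(last_value), sep = "_")
}

#' App-usage covariates for the adjusted models
#'
#' @param sugar_dates the user's post-creation sugar event dates.
#' @param first_hba1c_date the user's first HbA1c measurement date.
#' @param creation_date account-creation date.
#' @return `list(sugar_weeks = weeks between first and last sugar event (0
#'   with fewer than 2 events), weeks_before_start = weeks from first HbA1c
#'   measurement to account creation (floored at 0), sugar_count)`.
#' @export
compute_usage_covariates <- function(sugar_dates, first_hba1c_date,
                                     creation_date) {
  n <- length(sugar_dates)
  sugar_weeks <- if (n >= 2) {
    as.numeric(max(sugar_dates) - min(sugar_dates)) / 7
  } else 0
  weeks_before_start <-
    max(0, as.numeric(creation_date - first_hba1c_date) / 7)
  list(sugar_weeks = sugar_weeks, weeks_before_start = weeks_before_start,
       sugar_count = n)
}

#' Per-user trend summaries for the whole cohort
#'
#' Computes, for every included cohort user with at least two dated
#' measurements, the OLS trend (slope, intercept, r-squared), decline, the
#' sample SD of raw values, measurement frequency (measurements per day of
#' span), the regulation class, and the app-usage covariates.
#'
#' @param cohort per-user tibble from [build_cohort()] (only rows with
#'   `exclusion_reason == "none"` are summarised).
#' @param hba1c validated HbA1c measurements.
#' @param users validated demographics.
#' @param log_events post-creation-filtered log events.
#' @param threshold regulation threshold, % (default 6.5).
#' @return tibble with one row per included user: `user_id`,
#'   `continuous_user`, `n_measurements`, `span_days`, `slope`, `intercept`,
#'   `decline`, `r_squared`, `sd`, `measure_frequency`, `days_before_start`,
#'   `first_value`, `last_value`, `regulation`, `sugar_weeks`,
#'   `weeks_before_start`, `sugar_count`, `age`, `sex`.
#' @export
compute_trend_summaries <- function(cohort, hba1c, users, log_events,
                                    threshold = 6.5) {
  included <- cohort[cohort$exclusion_reason == "none", , drop = FALSE]
  hb_by_user <- split(hba1c[, c("measure_date", "value")], hba1c$user_id)
  sugar <- log_events[log_events$`function` == "sugar", , drop = FALSE]
  sugar_by_user <- split(sugar$event_date, sugar$user_id)
  u <- users[match(included$user_id, users$user_id), , drop = FALSE]

  n <- nrow(included)
  cols <- list(n_measurements = integer(n), span_days = numeric(n),
               slope = numeric(n), intercept = numeric(n),
               decline = numeric(n), r_squared = numeric(n), sd = numeric(n),
               measure_frequency = numeric(n), days_before_start = numeric(n),
               first_value = numeric(n), last_value = numeric(n),
               sugar_weeks = numeric(n), weeks_before_start = numeric(n),
               sugar_count = integer(n))
  for (i in seq_len(n)) {
    uid <- included$user_id[i]
    hb <- hb_by_user[[uid]]
    hb <- hb[order(hb$measure_date), , drop = FALSE]
    day <- as.numeric(hb$measure_date - hb$measure_date[1])
    trend <- fit_trend(day, hb$value)
    span <- day[length(day)]
    disp <- compute_dispersion(hb$value)
    usage <- compute_usage_covariates(
      sugar_by_user[[uid]] %||% as.Date(character()),
      hb$measure_date[1], u$account_creation_date[i])
    cols$n_measurements[i] <- nrow(hb)
    cols$span_days[i] <- span
    cols$slope[i] <- trend$slope
    cols$intercept[i] <- trend$intercept
    cols$decline[i] <- compute_decline(trend$slope, span)
    cols$r_squared[i] <- trend$r_squared
    cols$sd[i] <- disp$sd
    cols$measure_frequency[i] <- nrow(hb) / span
    cols$days_before_start[i] <-
      as.numeric(u$account_creation_date[i] - hb$measure_date[1])
    cols$first_value[i] <- disp$first_value
    cols$last_value[i] <- disp$last_value
    cols$sugar_weeks[i] <- usage$sugar_weeks
    cols$weeks_before_start[i] <- usage$weeks_before_start
    cols$sugar_count[i] <- usage$sugar_count
  }
  tibble::tibble(
    user_id = as.character(included$user_id),
    continuous_user = as.logical(included$continuous_user),
    n_measurements = cols$n_measurements, span_days = cols$span_days,
    slope = cols$slope, intercept = cols$intercept, decline = cols$decline,
    r_squared = cols$r_squared, sd = cols$sd,
    measure_frequency = cols$measure_frequency,
    days_before_start = cols$days_before_start,
    first_value = cols$first_value, last_value = cols$last_value,
    regulation = classify_regulation(cols$first_value, cols$last_value,
                                     threshold),
    sugar_weeks = cols$sugar_weeks,
    weeks_before_start = cols$weeks_before_start,
    sugar_count = cols$sugar_count,
    age = as.numeric(u$age), sex = as.character(u$sex))
}
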