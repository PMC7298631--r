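# Synthetic PHR-log + EMR generator.
#
# The generator's stated world is the published cohort: two engagement groups
# (continuous / noncontinuous app users) whose demographic, laboratory and
# engagement summaries default to the study's printed group statistics. Every
# user carries ground-truth labels (intended group, intended decline, intended
# DCSI) so the downstream classifier, scorer and trend fitter can be verified
# by round trip.

.study_windows <- list(
  creation_min = as.Date("2015-12-01"),
  creation_max = as.Date("2018-04-30"),
  hba1c_min    = as.Date("2014-01-01"),
  hba1c_max    = as.Date("2018-11-30")
)

#' Per-group generator parameters
#'
#' One block of group-level parameters for [generator_config()]. Defaults are
#' supplied by `generator_config()` and equal the published group statistics
#' (continuous n=133 / noncontinuous n=7320 cohort).
#'
#' @param age_mean,age_sd age at account creation, years (truncated at 18).
#' @param male_prop proportion of male users, in `[0, 1]`.
#' @param first_hba1c_mean,first_hba1c_sd first HbA1c measurement, %.
#' @param n_meas_mean,n_meas_sd number of HbA1c measurements (min 2).
#' @param span_days_mean,span_days_sd days between first and last HbA1c
#'   measurement (truncated to more than 100 days, the inclusion rule).
#' @param decline_mean,decline_sd the span-normalised trend statistic
#'   (slope in %/day times span / 100); unitless.
#' @param hba1c_noise_sd measurement noise around the linear trend, %.
#' @param days_before_start_mean,days_before_start_sd days between the first
#'   HbA1c measurement and account creation.
#' @param diabetes_code_prob probability a user carries an uncomplicated
#'   ICD-10 diabetes code (E08--E13 root).
#' @param complication_probs named probabilities of carrying at least one
#'   diagnosis in each of the seven DCSI complication categories.
#' @param sugar_user_prob probability the user ever enters blood-glucose
#'   ("sugar") diary data.
#' @param sugar_count_meanlog,sugar_count_sdlog log-normal parameters of the
#'   per-user sugar event count for continuous users (median `exp(meanlog)`).
#' @param burst_count_lambda Poisson rate for the small event bursts of
#'   noncontinuous users (count is `1 + Poisson(lambda)`).
#' @param calendar_user_prob probability the user ever uses the diabetes
#'   calendar function.
#' @param calendar_count_meanlog,calendar_count_sdlog log-normal parameters of
#'   the per-user calendar event count for continuous users.
#' @return a named list of class `phr_group_params`.
#' @export
group_params <- function(age_mean, age_sd, male_prop,
                         first_hba1c_mean, first_hba1c_sd,
                         n_meas_mean, n_meas_sd,
                         span_days_mean, span_days_sd,
                         decline_mean, decline_sd,
                         hba1c_noise_sd,
                         days_before_start_mean, days_before_start_sd,
                         diabetes_code_prob,
                         complication_probs,
                         sugar_user_prob,
                         sugar_count_meanlog = log(97),
                         sugar_count_sdlog = 1.086,
                         burst_count_lambda = 4,
                         calendar_user_prob = sugar_user_prob,
                         calendar_count_meanlog = log(67),
                         calendar_count_sdlog = 1.054) {
  p <- list(
    age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
    first_hba1c_mean = first_hba1c_mean, first_hba1c_sd = first_hba1c_sd,
    n_meas_mean = n_meas_mean, n_meas_sd = n_meas_sd,
    span_days_mean = span_days_mean, span_days_sd = span_days_sd,
    decline_mean = decline_mean, decline_sd = decline_sd,
    hba1c_noise_sd = hba1c_noise_sd,
    days_before_start_mean = days_before_start_mean,
    days_before_start_sd = days_before_start_sd,
    diabetes_code_prob = diabetes_code_prob,
    complication_probs = complication_probs,
    sugar_user_prob = sugar_user_prob,
    sugar_count_meanlog = sugar_count_meanlog,
    sugar_count_sdlog = sugar_count_sdlog,
    burst_count_lambda = burst_count_lambda,
    calendar_user_prob = calendar_user_prob,
    calendar_count_meanlog = calendar_count_meanlog,
    calendar_count_sdlog = calendar_count_sdlog
  )
  for (nm in c("age_sd", "first_hba1c_sd", "n_meas_sd", "span_days_sd",
               "decline_sd", "hba1c_noise_sd", "days_before_start_sd",
               "sugar_count_sdlog", "calendar_count_sdlog",
               "burst_count_lambda")) {
    check_nonneg(p[[nm]], nm)
  }
  for (nm in c("male_prop", "diabetes_code_prob", "sugar_user_prob",
               "calendar_user_prob")) {
    check_prob(p[[nm]], nm)
  }
  check_prob(p$complication_probs, "complication_probs")
  if (!setequal(names(p$complication_probs), dcsi_categories())) {
    abort(paste0("`complication_probs` must be named with the seven DCSI ",
                 "categories: ", paste(dcsi_categories(), collapse = ", ")),
          class = "phr_config_error")
  }
  structure(p, class = "phr_group_params")
}

#' Generator configuration
#'
#' Builds the full configuration of the synthetic-cohort generator. Defaults
#' equal the published study's group statistics: continuous users n=133
#' (age 53.59 +/- 9.89 y, 82.7% male, first HbA1c 7.86 +/- 1.78%, 12.44
#' measurements over 1254 days, decline -0.00533 +/- 0.0144) and
#' noncontinuous users n=7320 (57.58 +/- 11.95 y, 66.37% male, 7.51 +/-
#' 1.62%, 11.90 measurements over 1336 days, decline -0.00278 +/- 0.0137).
#'
#' `decline_cor` encodes how the per-user decline co-varies with the first
#' HbA1c value, the pre-app measurement history and age (correlations on the
#' standardised scale; the residual SD is shrunk so the marginal SD stays at
#' `decline_sd`). The default first-HbA1c correlation of -0.54 is the value
#' implied by the published ANCOVA F statistic for that covariate at the
#' study's sample size.
#'
#' @param n_continuous,n_noncontinuous group sizes (defaults 133 / 7320).
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param continuous,noncontinuous [group_params()] blocks.
#' @param decline_cor named numeric correlations of decline with
#'   `first_hba1c`, `days_before_start` and `age`; squared sum must be < 1.
#' @return a list of class `phr_generator_config`.
#' @export
generator_config <- function(n_continuous = 133,
                             n_noncontinuous = 7320,
                             seed = 1L,
                             continuous = group_params(
                               age_mean = 53.59, age_sd = 9.89,
                               male_prop = 0.827,
                               first_hba1c_mean = 7.86, first_hba1c_sd = 1.78,
                               n_meas_mean = 12.44, n_meas_sd = 6.90,
                               span_days_mean = 1254, span_days_sd = 461,
                               decline_mean = -0.00533, decline_sd = 0.0144,
                               hba1c_noise_sd = 0.70,
                               days_before_start_mean = 546,
                               days_before_start_sd = 348,
                               diabetes_code_prob = 1.0,
                               complication_probs = c(
                                 retinopathy = 0.233, nephropathy = 0.098,
                                 neuropathy = 0.173, cerebrovascular = 0.150,
                                 cardiovascular = 0.120,
                                 peripheral_vascular = 0.008,
                                 metabolic = 0.008),
                               sugar_user_prob = 1.0),
                             noncontinuous = group_params(
                               age_mean = 57.58, age_sd = 11.95,
                               male_prop = 0.6637,
                               first_hba1c_mean = 7.51, first_hba1c_sd = 1.62,
                               n_meas_mean = 11.90, n_meas_sd = 6.82,
                               span_days_mean = 1336, span_days_sd = 445,
                               decline_mean = -0.00278, decline_sd = 0.0137,
                               hba1c_noise_sd = 0.60,
                               days_before_start_mean = 712,
                               days_before_start_sd = 377,
                               diabetes_code_prob = 1.0,
                               complication_probs = c(
                                 retinopathy = 0.2071, nephropathy = 0.1045,
                                 neuropathy = 0.1731, cerebrovascular = 0.1300,
                                 cardiovascular = 0.1870,
                                 peripheral_vascular = 0.008,
                                 metabolic = 0.005),
                               sugar_user_prob = 0.0395,
                               calendar_user_prob = 0.0406),
                             decline_cor = c(first_hba1c = -0.54,
                                             days_before_start = 0.14,
                                             age = 0.03)) {
  check_count(n_continuous, "n_continuous")
  check_count(n_noncontinuous, "n_noncontinuous")
  check_count(abs(as.integer(seed)), "abs(seed)")
  stopifnot(inherits(continuous, "phr_group_params"),
            inherits(noncontinuous, "phr_group_params"))
  if (!all(c("first_hba1c", "days_before_start", "age") %in% names(decline_cor))) {
    abort("`decline_cor` needs first_hba1c, days_before_start and age entries.",
          class = "phr_config_error")
  }
  if (sum(decline_cor^2) >= 1) {
    abort("`decline_cor` correlations imply non-positive residual variance.",
          class = "phr_config_error")
  }
  structure(
    list(n_continuous = as.integer(n_continuous),
         n_noncontinuous = as.integer(n_noncontinuous),
         seed = as.integer(seed),
         continuous = continuous, noncontinuous = noncontinuous,
         decline_cor = decline_cor),
    class = "phr_generator_config"
  )
}

#' Simulate one HbA1c trajectory
#'
#' Measurement days are spread over exactly `span_days`: first and last day
#' fixed at 0 and `span_days`, interior days evenly spaced with uniform jitter
#' of `jitter_frac` times the inter-measurement gap. Values follow the line
#' with slope `decline_target * 100 / span_days` (%/day) plus Gaussian noise,
#' clipped to the plausible assay range 4--16%. With zero noise the fitted
#' least-squares decline equals `decline_target` exactly; with noise its
#' expectation does.
#'
#' @param first_value HbA1c at day 0, %.
#' @param decline_target intended decline (slope x span / 100), unitless.
#' @param span_days days between first and last measurement (> 0).
#' @param n_meas number of measurements (>= 2).
#' @param noise_sd measurement noise SD, % (>= 0).
#' @param jitter_frac jitter of interior measurement days as a fraction of the
#'   even gap (default 0.1; use 0 for deterministic day grids).
#' @return a tibble with columns `day` (integer offset from the first
#'   measurement) and `value` (%).
#' @export
generate_trajectory <- function(first_value, decline_target, span_days, n_meas,
                                noise_sd = 0, jitter_frac = 0.1) {
  if (n_meas < 2) abort("`n_meas` must be >= 2.", class = "phr_argument_error")
  if (span_days <= 0) abort("`span_days` must be > 0.", class = "phr_argument_error")
  check_nonneg(noise_sd, "noise_sd")
  tv <- traj_days_values(first_value, decline_target, span_days,
                         as.integer(n_meas), noise_sd, jitter_frac)
  tibble::tibble(day = tv$day, value = tv$value)
}

# cheap internal kernel shared with the dataset generator (no tibble cost)
traj_days_values <- function(first_value, decline_target, span_days, n_meas,
                             noise_sd, jitter_frac) {
  if (n_meas == 2) {
    day <- c(0, span_days)
  } else {
    gap <- span_days / (n_meas - 1)
    inner <- gap * seq_len(n_meas - 2) +
      runif(n_meas - 2, -jitter_frac * gap, jitter_frac * gap)
    day <- c(0, sort(pmin(pmax(round(inner), 1), span_days - 1)), span_days)
  }
  slope <- decline_target * 100 / span_days
  value <- first_value + slope * day
  if (noise_sd > 0) value <- value + rnorm(n_meas, 0, noise_sd)
  list(day = as.integer(round(day)), value = pmin(pmax(value, 4), 16))
}

#' Simulate one user's blood-glucose diary events
#'
#' Continuous users are built to satisfy the weekly-use rule by construction:
#' the first event lands on day 0 and one event is placed in each of at least
#' four consecutive 7-day bins from the first event, with any further events
#' scattered over the horizon (extra events can never break the rule).
#' Noncontinuous emitters are built to violate it: all their events fall
#' inside a single 13-day burst, which can occupy at most two 7-day bins.
#'
#' @param is_continuous logical; should the emitted events satisfy the
#'   continuous-use rule?
#' @param first_event_date `Date`; day 0 of the user's engagement (at or after
#'   account creation).
#' @param horizon_days days available for events; must be >= 28 when
#'   `is_continuous`.
#' @param n_events optional event count; drawn from the group defaults when
#'   `NULL` (log-normal with median 97 for continuous users, `1 + Poisson(4)`
#'   for noncontinuous emitters).
#' @param params optional [group_params()] block supplying count parameters.
#' @return tibble of log events (`function` = "sugar", `event_date`).
#' @export
generate_engagement <- function(is_continuous, first_event_date, horizon_days,
                                n_events = NULL, params = NULL) {
  horizon_days <- as.integer(horizon_days)
  if (is_continuous && horizon_days < 28) {
    abort("continuous engagement needs a horizon of at least 28 days.",
          class = "phr_argument_error")
  }
  days <- sugar_event_days(is_continuous, horizon_days, n_events, params)
  if (length(days) == 0) return(empty_log_events())
  tibble::tibble(`function` = "sugar",
                 event_date = first_event_date + sort(days))
}

# cheap internal kernel shared with the dataset generator
sugar_event_days <- function(is_continuous, horizon_days, n_events = NULL,
                             params = NULL) {
  if (is_continuous) {
    meanlog <- params$sugar_count_meanlog %||% log(97)
    sdlog <- params$sugar_count_sdlog %||% 1.086
    if (is.null(n_events)) n_events <- max(4L, round(rlnorm(1, meanlog, sdlog)))
    n_events <- max(4L, as.integer(n_events))
    max_weeks <- horizon_days %/% 7L
    streak <- min(max_weeks, 4L + rpois(1, 8))
    days <- c(0L, 7L * seq_len(streak - 1L) +
                sample.int(7L, streak - 1L, replace = TRUE) - 1L)
    extra <- n_events - streak
    if (extra > 0) {
      days <- c(days, sample.int(horizon_days, extra, replace = TRUE) - 1L)
    }
  } else {
    lambda <- params$burst_count_lambda %||% 4
    if (is.null(n_events)) n_events <- 1L + rpois(1, lambda)
    if (n_events <= 0) return(integer())
    start <- sample.int(max(1L, horizon_days - 12L), 1) - 1L
    days <- start + sample.int(13L, n_events, replace = TRUE) - 1L
    days <- pmin(days, max(horizon_days - 1L, 0L))
  }
  days
}

empty_log_events <- function() {
  tibble::tibble(`function` = character(), event_date = as.Date(character()))
}

empty_dataset <- function(config) {
  structure(list(
    users = tibble::tibble(user_id = character(),
                           account_creation_date = as.Date(character()),
                           age = numeric(), sex = character()),
    log_events = tibble::tibble(user_id = character(), `function` = character(),
                                event_date = as.Date(character())),
    hba1c = tibble::tibble(user_id = character(),
                           measure_date = as.Date(character()),
                           value = numeric()),
    diagnoses = tibble::tibble(user_id = character(), icd10_code = character(),
                               diagnosis_date = as.Date(character())),
    truth = tibble::tibble(user_id = character(), group = character(),
                           decline_target = numeric(), dcsi_total = integer(),
                           n_meas = integer(), span_days = integer()),
    config = config
  ), class = "phr_dataset")
}

# One group's users, vectorised where the draws are exchangeable; the
# per-user trajectory and event kernels run in plain-R loops over cheap
# numeric vectors (no per-user tibble construction).
generate_group <- function(ids, grp, p, cor, mapping) {
  n <- length(ids)
  w <- .study_windows
  creation <- w$creation_min +
    sample.int(as.integer(w$creation_max - w$creation_min) + 1L, n,
               replace = TRUE) - 1L
  dbs_upper <- as.numeric(creation - w$hba1c_min)
  dbs <- round(rnorm_trunc(n, p$days_before_start_mean,
                           p$days_before_start_sd, 0, dbs_upper))
  first_date <- creation - dbs
  span_lower <- pmax(101, dbs + 29)
  span_upper <- as.numeric(w$hba1c_max - first_date)
  span <- round(rnorm_trunc(n, p$span_days_mean, p$span_days_sd,
                            span_lower, span_upper))
  age <- rnorm_trunc(n, p$age_mean, p$age_sd, 18, Inf)
  sex <- ifelse(runif(n) < p$male_prop, "male", "female")
  first_hba1c <- rnorm_trunc(n, p$first_hba1c_mean, p$first_hba1c_sd, 4, 16)
  n_meas <- pmax(2L, round(rnorm_trunc(n, p$n_meas_mean, p$n_meas_sd, 2, Inf)))

  # standardise in-sample: truncation shifts the nominal means (notably for
  # days-before-start), and the decline-covariate link must not move the
  # group's marginal decline mean away from decline_mean
  zstd <- function(x, fallback_sd) {
    s <- if (n > 1) sd(x) else 0
    if (!is.finite(s) || s == 0) s <- fallback_sd
    (x - mean(x)) / s
  }
  z <- cbind(first_hba1c = zstd(first_hba1c, p$first_hba1c_sd),
             days_before_start = zstd(dbs, p$days_before_start_sd),
             age = zstd(age, p$age_sd))
  resid_scale <- sqrt(1 - sum(cor^2))
  decline <- p$decline_mean + p$decline_sd *
    (as.vector(z %*% cor[colnames(z)]) + resid_scale * rnorm(n))

  continuous <- identical(grp, "continuous")
  horizon <- pmax(span - dbs, 1)
  is_sugar_user <- if (continuous) rep(TRUE, n) else runif(n) < p$sugar_user_prob
  is_cal_user <- runif(n) < p$calendar_user_prob
  has_dm_code <- runif(n) < p$diabetes_code_prob
  dm_root <- sample(c("E11", "E10", "E13", "E08", "E09"), n, replace = TRUE,
                    prob = c(0.70, 0.15, 0.08, 0.04, 0.03))
  pools <- lapply(setNames(nm = dcsi_categories()), function(cat) {
    list(mapping$code[mapping$category == cat & mapping$severity == 1L],
         mapping$code[mapping$category == cat & mapping$severity == 2L])
  })

  hb_day <- vector("list", n); hb_val <- vector("list", n)
  ev_day <- vector("list", n); ev_fun <- vector("list", n)
  dx_code <- vector("list", n); dx_day <- vector("list", n)
  dcsi_total <- integer(n)
  for (i in seq_len(n)) {
    tv <- traj_days_values(first_hba1c[i], decline[i], span[i], n_meas[i],
                           p$hba1c_noise_sd, 0.1)
    hb_day[[i]] <- tv$day
    hb_val[[i]] <- tv$value

    days <- integer(); funs <- character()
    if (is_sugar_user[i]) {
      days <- sugar_event_days(continuous, horizon[i], params = p)
      funs <- rep("sugar", length(days))
    }
    if (is_cal_user[i]) {
      n_cal <- if (continuous) {
        max(1L, round(rlnorm(1, p$calendar_count_meanlog,
                             p$calendar_count_sdlog)))
      } else 1L + rpois(1, p$burst_count_lambda)
      days <- c(days, sample.int(horizon[i], n_cal, replace = TRUE) - 1L)
      funs <- c(funs, rep("diabetes_calendar", n_cal))
    }
    ev_day[[i]] <- days; ev_fun[[i]] <- funs

    dx <- if (has_dm_code[i]) paste0(dm_root[i], ".9") else character()
    tot <- 0L
    comp <- runif(7) < p$complication_probs[dcsi_categories()]
    for (k in which(comp)) {
      cat <- dcsi_categories()[k]
      sev <- if (cat == "neuropathy") 1L else sample(1:2, 1, prob = c(0.8, 0.2))
      pool <- pools[[cat]][[sev]]
      dx <- c(dx, pool[sample.int(length(pool), 1)])
      tot <- tot + sev
    }
    dcsi_total[i] <- tot
    dx_code[[i]] <- dx
    dx_day[[i]] <- if (length(dx) > 0) {
      sample.int(span[i], length(dx), replace = TRUE) - 1L
    } else integer()
  }

  hb_rep <- rep.int(seq_len(n), lengths(hb_day))
  ev_rep <- rep.int(seq_len(n), lengths(ev_day))
  dx_rep <- rep.int(seq_len(n), lengths(dx_code))
  list(
    users = tibble::tibble(user_id = ids, account_creation_date = creation,
                           age = age, sex = sex),
    hba1c = tibble::tibble(
      user_id = ids[hb_rep],
      measure_date = first_date[hb_rep] + unlist(hb_day, use.names = FALSE),
      value = unlist(hb_val, use.names = FALSE)),
    log_events = tibble::tibble(
      user_id = ids[ev_rep],
      `function` = unlist(ev_fun, use.names = FALSE) %||% character(),
      event_date = creation[ev_rep] + unlist(ev_day, use.names = FALSE)),
    diagnoses = tibble::tibble(
      user_id = ids[dx_rep],
      icd10_code = unlist(dx_code, use.names = FALSE) %||% character(),
      diagnosis_date = first_date[dx_rep] + unlist(dx_day, use.names = FALSE)),
    truth = tibble::tibble(user_id = ids, group = grp,
                           decline_target = decline,
                           dcsi_total = dcsi_total,
                           n_meas = as.integer(n_meas),
                           span_days = as.integer(span))
  )
}

#' Generate a synthetic PHR + EMR dataset
#'
#' Draws `n_continuous + n_noncontinuous` users with demographics, dated HbA1c
#' trajectories, app-log events and ICD-10 diagnoses whose group-level
#' statistics default to the published cohort's. Continuous users' sugar
#' events satisfy the weekly-use rule by construction; noncontinuous users'
#' events violate it by construction, so the engagement classifier can be
#' checked by round trip against `truth$group`.
#'
#' @param config a [generator_config()].
#' @return an object of class `phr_dataset`: a list of tibbles `users`,
#'   `log_events`, `hba1c`, `diagnoses`, the ground-truth table `truth`
#'   (intended group, decline, DCSI), and the `config` used.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "phr_generator_config")) {
    abort("`config` must come from generator_config().",
          class = "phr_config_error")
  }
  n_total <- config$n_continuous + config$n_noncontinuous
  if (n_total == 0) return(empty_dataset(config))
  mapping <- dcsi_default_mapping()
  withr::with_seed(config$seed, {
    ids <- sprintf("U%06d", seq_len(n_total))
    recs <- list()
    if (config$n_continuous > 0) {
      recs$cont <- generate_group(ids[seq_len(config$n_continuous)],
                                  "continuous", config$continuous,
                                  config$decline_cor, mapping)
    }
    if (config$n_noncontinuous > 0) {
      recs$noncont <- generate_group(
        ids[config$n_continuous + seq_len(config$n_noncontinuous)],
        "noncontinuous", config$noncontinuous, config$decline_cor, mapping)
    }
    bind_part <- function(nm) {
      purrr::list_rbind(purrr::map(recs, nm))
    }
    structure(list(
      users = bind_part("users"),
      log_events = bind_part("log_events"),
      hba1c = bind_part("hba1c"),
      diagnoses = bind_part("diagnoses"),
      truth = bind_part("truth"),
      config = config
    ), class = "phr_dataset")
  })
}

#' @export
print.phr_dataset <- function(x, ...) {
  cat(sprintf(
    "<phr_dataset> %d users (%d continuous / %d noncontinuous by truth)\n",
    nrow(x$users), sum(x$truth$group == "continuous"),
    sum(x$truth$group == "noncontinuous")))
  cat(sprintf("  %d log events, %d HbA1c measurements, %d diagnoses\n",
              nrow(x$log_events), nrow(x$hba1c), nrow(x$diagnoses)))
  invisible(x)
}

#' Write a synthetic dataset as the pipeline's CSV inputs
#'
#' Emits `users.csv`, `log.csv`, `hba1c.csv`, `diagnoses.csv` (and
#' `truth.csv`) in the exact dialect the ingest readers expect: comma
#' separated, UTF-8, ISO-8601 dates, header row.
#'
#' @param dataset a `phr_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(users = file.path(dir, "users.csv"),
             log = file.path(dir, "log.csv"),
             hba1c = file.path(dir, "hba1c.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(dataset$users, paths["users"])
  readr::write_csv(dataset$log_events, paths["log"])
  readr::write_csv(dataset$hba1c, paths["hba1c"])
  readr::write_csv(dataset$diagnoses, paths["diagnoses"])
  readr::write_csv(dataset$truth, paths["truth"])
  invisible(paths)
}
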