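# Report assembly: group-characteristics table, adjusted-model tables, the
# regulation 2x2-by-group table, the decline-pattern figure summary, the
# inclusion-flow counts, and the end-to-end pipeline driver.

summarise_count_row <- function(variable, x_total, y_total) {
  tibble::tibble(variable = variable, test = NA_character_,
                 continuous = format(x_total, big.mark = ","),
                 noncontinuous = format(y_total, big.mark = ","),
                 statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                 low_expected = FALSE)
}

#' Group-characteristics table (demographics, engagement, labs, DCSI)
#'
#' One row per compared variable, with the summary type and test used in the
#' source analysis: Student t for age and the HbA1c measurement-cadence
#' variables; Wilcoxon rank-sum (plus Mood's median test) for the per-user
#' app-event counts; Wilcoxon for measure frequency, first HbA1c and DCSI
#' score; pooled z for all proportions; chi-square for the sex split and the
#' DCSI score distribution (categories empty in both groups dropped).
#'
#' @param metrics per-user tibble from [compute_trend_summaries()].
#' @param dcsi per-user tibble from [score_dcsi()] covering the same users.
#' @param log_events post-creation-filtered log events (for diabetes-calendar
#'   counts).
#' @return tibble of comparison rows.
#' @export
build_table1 <- function(metrics, dcsi, log_events) {
  if (nrow(metrics) == 0) {
    abort("empty metrics table.", class = "phr_argument_error")
  }
  g <- metrics$continuous_user
  dc <- dcsi[match(metrics$user_id, dcsi$user_id), , drop = FALSE]
  if (anyNA(dc$total)) abort("missing DCSI scores for some cohort users.",
                             class = "phr_argument_error")
  cal <- log_events[log_events$`function` == "diabetes_calendar", , drop = FALSE]
  cal_n <- table(factor(cal$user_id, levels = metrics$user_id))
  cal_count <- as.integer(cal_n)

  sp <- function(v) list(x = v[g], y = v[!g])
  rows <- list(
    compare_groups(sp(metrics$age)$x, sp(metrics$age)$y, "continuous",
                   test = "t", variable = "age_years"),
    compare_groups(sp(metrics$sex)$x, sp(metrics$sex)$y, "categorical",
                   test = "chi_square", variable = "sex"),
    compare_groups(sp(metrics$sugar_count > 0)$x, sp(metrics$sugar_count > 0)$y,
                   "proportion", variable = "sugar_any_data"),
    summarise_count_row("sugar_total_data", sum(metrics$sugar_count[g]),
                        sum(metrics$sugar_count[!g])),
    compare_groups(sp(metrics$sugar_count)$x, sp(metrics$sugar_count)$y,
                   "continuous", test = "wilcoxon",
                   variable = "sugar_individual_count"),
    compare_groups(sp(metrics$sugar_count)$x, sp(metrics$sugar_count)$y,
                   "continuous", test = "median",
                   variable = "sugar_individual_count_median_test"),
    compare_groups(sp(cal_count > 0)$x, sp(cal_count > 0)$y,
                   "proportion", variable = "calendar_any_data"),
    summarise_count_row("calendar_total_data", sum(cal_count[g]),
                        sum(cal_count[!g])),
    compare_groups(sp(cal_count)$x, sp(cal_count)$y, "continuous",
                   test = "wilcoxon", variable = "calendar_individual_count"),
    compare_groups(sp(cal_count)$x, sp(cal_count)$y, "continuous",
                   test = "median",
                   variable = "calendar_individual_count_median_test"),
    compare_groups(sp(metrics$n_measurements)$x, sp(metrics$n_measurements)$y,
                   "continuous", test = "t", variable = "hba1c_n_measurements"),
    compare_groups(sp(metrics$measure_frequency)$x,
                   sp(metrics$measure_frequency)$y, "continuous",
                   test = "wilcoxon", variable = "hba1c_measure_frequency"),
    compare_groups(sp(metrics$span_days)$x, sp(metrics$span_days)$y,
                   "continuous", test = "t", variable = "hba1c_measurement_days"),
    compare_groups(sp(metrics$days_before_start)$x,
                   sp(metrics$days_before_start)$y, "continuous", test = "t",
                   variable = "measurement_days_before_start"),
    compare_groups(sp(metrics$first_value >= 6.5)$x,
                   sp(metrics$first_value >= 6.5)$y, "proportion",
                   variable = "first_hba1c_ge_6.5"),
    compare_groups(sp(metrics$first_value)$x, sp(metrics$first_value)$y,
                   "continuous", test = "wilcoxon", variable = "first_hba1c"),
    compare_groups(sp(dc$total)$x, sp(dc$total)$y, "continuous",
                   test = "wilcoxon", variable = "dcsi_score"),
    compare_groups(sp(dc$total)$x, sp(dc$total)$y, "categorical",
                   test = "chi_square", variable = "dcsi_distribution")
  )
  for (cat in dcsi_categories()) {
    pres <- dc[[paste0(cat, "_present")]]
    rows[[length(rows) + 1L]] <- compare_groups(
      sp(pres)$x, sp(pres)$y, "proportion",
      variable = paste0("complication_", cat))
  }
  purrr::list_rbind(rows)
}

#' Regulation 2x2-by-group table
#'
#' Counts and percentages of the four (first, last) threshold classes per
#' engagement group, with a cell-wise pooled two-proportion z test per class
#' (the omnibus construction is ambiguous in the source; cell-wise is
#' labelled as such by the `test` column).
#'
#' @param metrics per-user tibble from [compute_trend_summaries()].
#' @return tibble with one row per regulation class: per-group `n`, `pct`
#'   (half-up, 1 decimal for the continuous group, 2 for the larger
#'   noncontinuous group), `statistic`, `p_value`.
#' @export
build_table3 <- function(metrics) {
  g <- metrics$continuous_user
  n1 <- sum(g); n2 <- sum(!g)
  classes <- c("low_low", "low_high", "high_low", "high_high")
  purrr::list_rbind(purrr::map(classes, function(cl) {
    x1 <- sum(metrics$regulation[g] == cl)
    x2 <- sum(metrics$regulation[!g] == cl)
    zt <- two_prop_z(x1, n1, x2, n2)
    tibble::tibble(regulation = cl, test = "z_proportion_cellwise",
                   continuous_n = x1, continuous_pct = proportion(x1, n1, 1),
                   noncontinuous_n = x2,
                   noncontinuous_pct = proportion(x2, n2, 2),
                   statistic = zt$statistic, p_value = zt$p_value)
  }))
}

#' Decline-pattern figure summary
#'
#' The underlying numbers of the decline-pattern figure: per group, the mean
#' trend-line intercept (fitted HbA1c at the first measurement) and the mean
#' decline. On an x-axis of percent-of-span, each patient's trend line has
#' slope equal to their decline, so the group mean line runs from the mean
#' intercept at 0% to `mean intercept + 100 * mean decline` at 100%.
#'
#' @param metrics per-user tibble from [compute_trend_summaries()].
#' @return tibble with one row per group: `group`, `n`, `mean_intercept`,
#'   `mean_decline`, `mean_r_squared`, `mean_sd`.
#' @export
figure3_summary <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(metrics,
                    group = ifelse(.data$continuous_user, "continuous",
                                   "noncontinuous")),
    n = dplyr::n(),
    mean_intercept = mean(.data$intercept),
    mean_decline = mean(.data$decline),
    mean_r_squared = mean(.data$r_squared),
    mean_sd = mean(.data$sd),
    .groups = "drop")
}

#' Minimal decline-pattern figure
#'
#' Per-patient trend lines (thin, on the percent-of-span x-axis) with the
#' group mean line overlaid, one panel per engagement group.
#'
#' @param metrics per-user tibble from [compute_trend_summaries()].
#' @param max_lines cap on per-patient background lines per group.
#' @return a ggplot object.
#' @export
plot_decline_lines <- function(metrics, max_lines = 200) {
  m <- dplyr::mutate(metrics,
                     group = ifelse(.data$continuous_user, "continuous",
                                    "noncontinuous"))
  m <- dplyr::slice_head(dplyr::group_by(m, .data$group), n = max_lines)
  m <- dplyr::ungroup(m)
  fig <- figure3_summary(metrics)
  ggplot2::ggplot(m) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = 100, y = .data$intercept,
                   yend = .data$intercept + 100 * .data$decline),
      alpha = 0.15, linetype = "dashed") +
    ggplot2::geom_segment(
      data = fig,
      ggplot2::aes(x = 0, xend = 100, y = .data$mean_intercept,
                   yend = .data$mean_intercept + 100 * .data$mean_decline),
      linewidth = 1, colour = "firebrick") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Percent of first-to-last measurement span",
                  y = "HbA1c (%)")
}

analysis_table <- function(metrics, dcsi) {
  dc <- dcsi[match(metrics$user_id, dcsi$user_id), , drop = FALSE]
  tibble::tibble(
    user_id = metrics$user_id,
    continuous_use = as.numeric(metrics$continuous_user),
    age = metrics$age,
    sex = as.numeric(metrics$sex == "male"),
    first_hba1c = metrics$first_value,
    dcsi = dc$total,
    sugar_weeks = metrics$sugar_weeks,
    weeks_before_start = metrics$weeks_before_start,
    sugar_count = metrics$sugar_count,
    decline = metrics$decline,
    first_value = metrics$first_value,
    last_value = metrics$last_value)
}

#' Self-consistency audit of a study report
#'
#' Verifies the inclusion-flow identities and recomputes every percentage in
#' the regulation table from its numerator and denominator.
#'
#' @param report a `phr_report`.
#' @return `TRUE` invisibly; aborts with a description on any inconsistency.
#' @export
audit_report <- function(report) {
  f <- report$flow_counts
  ok <- f$n_accounts == f$n_inappropriate + f$n_appropriate &&
    f$n_appropriate == f$n_no_diabetes + f$n_diabetes &&
    f$n_diabetes == f$n_continuous + f$n_noncontinuous
  if (!ok) abort("flow-count identities violated.", class = "phr_audit_error")
  t3 <- report$table3
  if (!is.null(t3) && nrow(t3) > 0) {
    n1 <- sum(t3$continuous_n); n2 <- sum(t3$noncontinuous_n)
    if (n1 != f$n_continuous || n2 != f$n_noncontinuous) {
      abort("regulation-table cells do not sum to the group sizes.",
            class = "phr_audit_error")
    }
    if (n1 > 0 &&
        !all(t3$continuous_pct == proportion(t3$continuous_n, n1, 1))) {
      abort("regulation-table percentages do not recompute.",
            class = "phr_audit_error")
    }
    if (n2 > 0 &&
        !all(t3$noncontinuous_pct == proportion(t3$noncontinuous_n, n2, 2))) {
      abort("regulation-table percentages do not recompute.",
            class = "phr_audit_error")
    }
  }
  invisible(TRUE)
}

#' Run the whole analysis pipeline
#'
#' Either generates a synthetic dataset from `config` or reads the four CSV
#' inputs from `input_dir`, then: filters pre-creation log events, builds the
#' cohort and inclusion flow, computes per-user trend summaries and DCSI
#' scores, and assembles the group-characteristics table, the decline /
#' r-squared / SD comparisons (Wilcoxon, as in the source analysis), the
#' ANCOVA, the regulation table, the logistic model, and the figure summary.
#' Deterministic given the configuration seed. The report is audited for
#' self-consistency before it is returned.
#'
#' @param config a [generator_config()] (ignored when `input_dir` is given).
#' @param input_dir directory with `users.csv`, `log.csv`, `hba1c.csv`,
#'   `diagnoses.csv` in the ingest dialect.
#' @param rule continuous-use rule, see [classify_continuous()].
#' @param threshold regulation threshold, % (default 6.5).
#' @param mode ingest validation mode.
#' @return an object of class `phr_report`: `flow_counts`, `cohort`,
#'   `metrics`, `table1`, `decline_comparisons`, `table2` (ANCOVA terms),
#'   `table3`, `table4` (logistic terms), `figure3_summary`, and `meta`
#'   (seed, rule, threshold, package version).
#' @export
run_pipeline <- function(config = generator_config(), input_dir = NULL,
                         rule = "anchored_bins", threshold = 6.5,
                         mode = "lenient") {
  if (is.null(input_dir)) {
    ds <- generate_dataset(config)
    users <- ds$users; log_events <- ds$log_events
    hba1c <- ds$hba1c; diagnoses <- ds$diagnoses
    seed <- config$seed
  } else {
    users <- read_users(file.path(input_dir, "users.csv"), mode)$data
    log_events <- read_log(file.path(input_dir, "log.csv"), mode)$data
    hba1c <- read_hba1c(file.path(input_dir, "hba1c.csv"), mode)$data
    diagnoses <- read_diagnoses(file.path(input_dir, "diagnoses.csv"),
                                mode)$data
    seed <- NA_integer_
  }
  log_post <- filter_post_creation(log_events, users)$data
  built <- build_cohort(users, log_post, hba1c, diagnoses, rule = rule)
  metrics <- compute_trend_summaries(built$cohort, hba1c, users, log_post,
                                     threshold)
  report <- structure(list(
    flow_counts = built$flow, cohort = built$cohort, metrics = metrics,
    table1 = NULL, decline_comparisons = NULL, table2 = NULL, table3 = NULL,
    table4 = NULL, figure3_summary = NULL,
    meta = list(seed = seed, rule = rule, threshold = threshold,
                ss_type = "II",
                package_version =
                  as.character(utils::packageVersion("phrglycemia")))),
    class = "phr_report")

  n1 <- sum(metrics$continuous_user)
  n2 <- sum(!metrics$continuous_user)
  if (nrow(metrics) == 0 || n1 == 0 || n2 == 0) {
    warn("cohort is empty or has an empty engagement group: only flow counts reported.")
    audit_report(report)
    return(report)
  }
  dcsi <- score_dcsi(diagnoses, user_ids = metrics$user_id)
  report$table1 <- build_table1(metrics, dcsi, log_post)
  g <- metrics$continuous_user
  report$decline_comparisons <- purrr::list_rbind(list(
    compare_groups(metrics$decline[g], metrics$decline[!g], "continuous",
                   test = "wilcoxon", variable = "decline"),
    compare_groups(metrics$r_squared[g], metrics$r_squared[!g], "continuous",
                   test = "wilcoxon", variable = "r_squared"),
    compare_groups(metrics$sd[g], metrics$sd[!g], "continuous",
                   test = "wilcoxon", variable = "sd")))
  tab <- analysis_table(metrics, dcsi)
  if (n1 >= 2 && n2 >= 2) {
    report$table2 <- tryCatch(fit_ancova(tab)$terms, error = function(e) {
      warn(sprintf("ANCOVA skipped: %s", conditionMessage(e))); NULL
    })
    report$table4 <- tryCatch(
      fit_regulation_logistic(tab, threshold)$terms,
      error = function(e) {
        warn(sprintf("logistic model skipped: %s", conditionMessage(e))); NULL
      })
  }
  report$table3 <- build_table3(metrics)
  report$figure3_summary <- figure3_summary(metrics)
  audit_report(report)
  report
}

#' @export
print.phr_report <- function(x, ...) {
  f <- x$flow_counts
  cat("<phr_report>\n")
  cat(sprintf("  accounts %d -> appropriate %d -> diabetes %d -> continuous %d / noncontinuous %d\n",
              f$n_accounts, f$n_appropriate, f$n_diabetes, f$n_continuous,
              f$n_noncontinuous))
  if (!is.null(x$figure3_summary)) {
    fs <- x$figure3_summary
    for (i in seq_len(nrow(fs))) {
      cat(sprintf("  %s: mean decline %.5f (n=%d)\n",
                  fs$group[i], fs$mean_decline[i], fs$n[i]))
    }
  }
  invisible(x)
}

#' Serialize a study report
#'
#' Writes `report.json` (flow counts, figure summary, metadata) plus one CSV
#' per table into `dir`.
#'
#' @param report a `phr_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "phr_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  master <- list(flow_counts = report$flow_counts,
                 figure3_summary = report$figure3_summary,
                 meta = report$meta)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(master, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, jp)
  for (nm in c("cohort", "metrics", "table1", "decline_comparisons",
               "table2", "table3", "table4", "figure3_summary")) {
    if (!is.null(report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(report[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
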