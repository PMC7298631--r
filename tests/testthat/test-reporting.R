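test_that("printed-style percentages use half-up rounding", {
  expect_equal(proportion(133, 7453, 2), 1.78)
  expect_equal(proportion(0, 10, 1), 0)
  expect_equal(proportion(110, 133, 1), 82.7)
  expect_equal(proportion(1, 200, 1), 0.5)
  expect_error(proportion(1, 0), class = "phr_argument_error")
  expect_error(proportion(5, 3), class = "phr_argument_error")
  # half-up, not banker's rounding
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-2.5), -3)
})

report_fixture <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- run_pipeline(generator_config(n_continuous = 40,
                                              n_noncontinuous = 400,
                                              seed = 314))
    }
    value
  }
})

test_that("the pipeline is deterministic and self-consistent", {
  rep1 <- report_fixture()
  rep2 <- run_pipeline(generator_config(n_continuous = 40,
                                        n_noncontinuous = 400, seed = 314))
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$table1, rep2$table1)
  expect_identical(rep1$table2, rep2$table2)
  expect_identical(rep1$table3, rep2$table3)
  expect_true(audit_report(rep1))
})

test_that("the characteristics table carries the expected tests and sums", {
  rep <- report_fixture()
  t1 <- rep$table1
  tests <- setNames(t1$test, t1$variable)
  expect_equal(tests[["age_years"]], "t")
  expect_equal(tests[["sex"]], "chi_square")
  expect_equal(tests[["sugar_any_data"]], "z_proportion")
  expect_equal(tests[["sugar_individual_count"]], "wilcoxon")
  expect_equal(tests[["sugar_individual_count_median_test"]], "median")
  expect_equal(tests[["hba1c_measure_frequency"]], "wilcoxon")
  expect_equal(tests[["dcsi_score"]], "wilcoxon")
  expect_true(is.na(tests[["sugar_total_data"]]))
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1, na.rm = TRUE))

  # the total sugar count is the sum of the groups' totals
  m <- rep$metrics
  expect_equal(
    sum(m$sugar_count),
    sum(m$sugar_count[m$continuous_user]) +
      sum(m$sugar_count[!m$continuous_user]))

  # male proportion of the continuous group near its generator target
  p_male <- mean(m$sex[m$continuous_user] == "male")
  n1 <- sum(m$continuous_user)
  expect_lt(abs(p_male - 0.827), 3 * sqrt(0.827 * 0.173 / n1))
})

test_that("the regulation table agrees with an independent tabulation", {
  rep <- report_fixture()
  t3 <- rep$table3
  m <- rep$metrics
  # independent route: threshold the raw first/last values directly
  want_high_low <- sum(m$first_value >= 6.5 & m$last_value < 6.5 &
                         m$continuous_user)
  expect_equal(t3$continuous_n[t3$regulation == "high_low"], want_high_low)
  expect_equal(sum(t3$continuous_n), sum(m$continuous_user))
  expect_equal(sum(t3$noncontinuous_n), sum(!m$continuous_user))
  expect_equal(t3$continuous_pct,
               proportion(t3$continuous_n, sum(t3$continuous_n), 1))
})

test_that("adjusted models in the report have the full covariate battery", {
  rep <- report_fixture()
  terms_expected <- c("continuous_use", "age", "sex", "first_hba1c", "dcsi",
                      "sugar_weeks", "weeks_before_start", "sugar_count")
  expect_equal(rep$table2$term, terms_expected)
  expect_equal(rep$table2$df_num, rep(1, 8))
  expect_equal(rep$table4$term, c("(Intercept)", terms_expected))
  expect_equal(rep$meta$ss_type, "II")
})

test_that("figure summary numbers restate the metrics", {
  rep <- report_fixture()
  fs <- rep$figure3_summary
  m <- rep$metrics
  expect_equal(fs$mean_decline[fs$group == "continuous"],
               mean(m$decline[m$continuous_user]))
  expect_equal(fs$mean_intercept[fs$group == "noncontinuous"],
               mean(m$intercept[!m$continuous_user]))
  p <- plot_decline_lines(m)
  expect_s3_class(p, "ggplot")
})

test_that("an empty generation yields an audited zero report, not a crash", {
  expect_warning(
    rep0 <- run_pipeline(generator_config(n_continuous = 0,
                                          n_noncontinuous = 0)),
    "empty")
  expect_equal(rep0$flow_counts$n_accounts, 0)
  expect_null(rep0$table1)
  expect_true(audit_report(rep0))
})

test_that("tampered reports fail the audit", {
  rep <- report_fixture()
  bad <- rep
  bad$table3$continuous_pct[1] <- bad$table3$continuous_pct[1] + 5
  expect_error(audit_report(bad), class = "phr_audit_error")
  bad2 <- rep
  bad2$flow_counts$n_continuous <- bad2$flow_counts$n_continuous + 1
  expect_error(audit_report(bad2), class = "phr_audit_error")
})

test_that("reports serialize to JSON + CSVs", {
  rep <- report_fixture()
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "table1.csv")))
  master <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(master$flow_counts$n_accounts, 440)
})
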