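test_that("empty and deterministic generation contracts hold", {
  empty <- generate_dataset(generator_config(n_continuous = 0,
                                             n_noncontinuous = 0))
  expect_s3_class(empty, "phr_dataset")
  expect_equal(nrow(empty$users), 0)
  expect_equal(nrow(empty$truth), 0)

  cfg <- generator_config(n_continuous = 15, n_noncontinuous = 60, seed = 1)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$users, b$users)
  expect_identical(a$hba1c, b$hba1c)
  expect_identical(a$log_events, b$log_events)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$truth, b$truth)
})

test_that("generator configs are validated", {
  expect_error(
    generator_config(continuous = group_params(
      age_mean = 50, age_sd = -1, male_prop = 0.8,
      first_hba1c_mean = 7.9, first_hba1c_sd = 1.8,
      n_meas_mean = 12, n_meas_sd = 7, span_days_mean = 1254,
      span_days_sd = 461, decline_mean = -0.005, decline_sd = 0.014,
      hba1c_noise_sd = 0.8, days_before_start_mean = 546,
      days_before_start_sd = 348, diabetes_code_prob = 1,
      complication_probs = c(retinopathy = 0.2, nephropathy = 0.1,
                             neuropathy = 0.17, cerebrovascular = 0.13,
                             cardiovascular = 0.19,
                             peripheral_vascular = 0.01, metabolic = 0.01),
      sugar_user_prob = 1)),
    class = "phr_config_error")
  expect_error(
    generator_config(continuous = group_params(
      age_mean = 50, age_sd = 10, male_prop = 1.2,
      first_hba1c_mean = 7.9, first_hba1c_sd = 1.8,
      n_meas_mean = 12, n_meas_sd = 7, span_days_mean = 1254,
      span_days_sd = 461, decline_mean = -0.005, decline_sd = 0.014,
      hba1c_noise_sd = 0.8, days_before_start_mean = 546,
      days_before_start_sd = 348, diabetes_code_prob = 1,
      complication_probs = c(retinopathy = 0.2, nephropathy = 0.1,
                             neuropathy = 0.17, cerebrovascular = 0.13,
                             cardiovascular = 0.19,
                             peripheral_vascular = 0.01, metabolic = 0.01),
      sugar_user_prob = 1)),
    class = "phr_config_error")
})

test_that("noiseless trajectories are exact lines with the target decline", {
  withr::local_seed(1)
  traj <- generate_trajectory(8.0, -0.01, 200, 3, noise_sd = 0,
                              jitter_frac = 0)
  expect_equal(traj$day, c(0L, 100L, 200L))
  expect_equal(traj$value, c(8.0, 7.5, 7.0))
  trend <- fit_trend(traj$day, traj$value)
  expect_equal(compute_decline(trend$slope, 200), -0.01)

  flat <- generate_trajectory(7.2, 0, 365, 5, noise_sd = 0, jitter_frac = 0)
  expect_true(all(flat$value == 7.2))

  expect_error(generate_trajectory(8, -0.01, 200, 1),
               class = "phr_argument_error")
  expect_error(generate_trajectory(8, -0.01, 0, 3),
               class = "phr_argument_error")
})

test_that("noisy trajectories recover the decline within analytic OLS error", {
  # oracle: closed-form sampling variance of the OLS slope at a fixed
  # even-day design, var(slope) = sigma^2 / Sxx, hence
  # var(decline) = var(slope) * (span/100)^2
  first <- 7.86; dec <- -0.00533; span <- 1254; n <- 12; sigma <- 0.3
  days <- round(seq(0, span, length.out = n))
  sxx <- sum((days - mean(days))^2)
  se_one <- sqrt(sigma^2 / sxx) * span / 100
  n_rep <- 500
  withr::local_seed(42)
  est <- replicate(n_rep, {
    traj <- generate_trajectory(first, dec, span, n, noise_sd = sigma,
                                jitter_frac = 0)
    trend <- fit_trend(traj$day, traj$value)
    compute_decline(trend$slope, span)
  })
  expect_lt(abs(mean(est) - dec), 3 * se_one / sqrt(n_rep))
  # the empirical spread should match the analytic one to ~15%
  expect_lt(abs(sd(est) - se_one) / se_one, 0.15)
})

test_that("engagement construction round-trips through the classifier", {
  withr::local_seed(7)
  origin <- as.Date("2016-03-01")
  for (i in 1:50) {
    ev <- generate_engagement(TRUE, origin, horizon_days = 200)
    expect_true(classify_continuous(ev$event_date))
    ev <- generate_engagement(FALSE, origin, horizon_days = 200)
    expect_false(classify_continuous(ev$event_date))
  }
  expect_error(generate_engagement(TRUE, origin, horizon_days = 20),
               class = "phr_argument_error")
})

test_that("continuous users' sugar event counts centre near the target median", {
  withr::local_seed(11)
  counts <- replicate(400, nrow(generate_engagement(
    TRUE, as.Date("2016-03-01"), horizon_days = 400)))
  expect_gt(median(counts), 70)
  expect_lt(median(counts), 130)
})

test_that("dataset invariants hold and group parameters are recovered", {
  ds <- small_dataset(n_cont = 400, n_noncont = 400, seed = 2024)
  # structural invariants
  creation <- ds$users$account_creation_date[
    match(ds$log_events$user_id, ds$users$user_id)]
  expect_true(all(ds$log_events$event_date >= creation))
  expect_true(all(ds$hba1c$value >= 4 & ds$hba1c$value <= 16))
  expect_true(all(ds$truth$user_id %in% ds$users$user_id))

  # parameter recovery within 3 SE per group
  cfg <- ds$config
  for (grp in c("continuous", "noncontinuous")) {
    p <- cfg[[grp]]
    idx <- ds$truth$group == grp
    uid <- ds$truth$user_id[idx]
    age <- ds$users$age[match(uid, ds$users$user_id)]
    expect_lt(abs(mean(age) - p$age_mean), 3 * sd(age) / sqrt(sum(idx)))
    dec <- ds$truth$decline_target[idx]
    expect_lt(abs(mean(dec) - p$decline_mean), 3 * sd(dec) / sqrt(sum(idx)))
    hb <- ds$hba1c[ds$hba1c$user_id %in% uid, ]
    hb <- hb[order(hb$user_id, hb$measure_date), ]
    first <- hb$value[!duplicated(hb$user_id)]
    expect_lt(abs(mean(first) - p$first_hba1c_mean),
              3 * sd(first) / sqrt(sum(idx)))
  }
})

test_that("complication prevalences recover the configured probabilities", {
  ds <- small_dataset(n_cont = 0, n_noncont = 600, seed = 31)
  scored <- score_dcsi(ds$diagnoses, user_ids = ds$users$user_id)
  probs <- ds$config$noncontinuous$complication_probs
  for (cat in c("retinopathy", "neuropathy", "cardiovascular")) {
    obs <- mean(scored[[paste0(cat, "_present")]])
    p <- probs[[cat]]
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 600))
  }
  expect_equal(scored$total[match(ds$truth$user_id, scored$user_id)],
               ds$truth$dcsi_total)
})
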