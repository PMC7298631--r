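d0 <- as.Date("2016-01-01")

test_that("appropriate-measurement and diabetes criteria follow the rules", {
  expect_false(is_appropriate_measurement(d0, d0))
  expect_false(is_appropriate_measurement(c(d0, d0 + 100), d0 + 50))
  expect_true(is_appropriate_measurement(c(d0, d0 + 150), d0 + 50))
  expect_true(is_appropriate_measurement(c(d0, d0 + 150), d0))
  expect_false(is_appropriate_measurement(c(d0, d0 + 150), d0 + 151))
  expect_false(is_appropriate_measurement(as.Date(character()), d0))

  expect_true(is_diabetic("E11.9", 6.0))
  expect_true(is_diabetic(character(), 6.5))
  expect_false(is_diabetic("E14", 6.4))
  expect_false(is_diabetic(character(), 6.49))
  expect_true(is_diabetic(c("I10", "E139"), 5.0))
})

test_that("the weekly-use rule is interpreted as anchored 7-day bins", {
  expect_true(classify_continuous(d0 + c(0, 7, 14, 21)))
  expect_false(classify_continuous(d0 + c(0, 14, 21, 28)))
  expect_true(classify_continuous(d0 + c(0, 3, 8, 16, 22, 27)))
  expect_false(classify_continuous(as.Date(character())))
  expect_false(classify_continuous(d0 + c(0, 1, 2)))

  # duplicate-day and order invariance
  ev <- d0 + c(21, 0, 7, 14, 7, 0)
  expect_true(classify_continuous(ev))
  expect_identical(classify_continuous(ev), classify_continuous(sort(ev)))

  # alternative readings agree on the canonical examples
  expect_true(classify_continuous(d0 + c(0, 7, 14, 21), rule = "window28"))
  expect_false(classify_continuous(d0 + c(0, 14, 21, 28), rule = "window28"))
  expect_true(classify_continuous(d0 + c(0, 3, 8, 16, 22, 27),
                                  rule = "window28"))
})

test_that("the window28 reading is monotone under adding events", {
  # (the anchored-bin reading is not: an earlier event can shift the bins)
  withr::local_seed(99)
  for (i in 1:200) {
    days <- sort(sample(0:120, sample(4:15, 1)))
    base <- classify_continuous(d0 + days, rule = "window28")
    more <- sort(c(days, sample(0:120, 3)))
    if (base) {
      expect_true(classify_continuous(d0 + more, rule = "window28"))
    }
  }
})

test_that("flow identities hold on generated, single-user and empty cohorts", {
  check_flow <- function(f) {
    expect_equal(f$n_accounts, f$n_inappropriate + f$n_appropriate)
    expect_equal(f$n_appropriate, f$n_no_diabetes + f$n_diabetes)
    expect_equal(f$n_diabetes, f$n_continuous + f$n_noncontinuous)
  }
  ds <- small_dataset(n_cont = 20, n_noncont = 60, seed = 5)
  post <- filter_post_creation(ds$log_events, ds$users)$data
  built <- build_cohort(ds$users, post, ds$hba1c, ds$diagnoses)
  check_flow(built$flow)

  # round trip: generated truth labels are reproduced exactly
  joined <- merge(built$cohort, ds$truth, by = "user_id")
  expect_true(all(joined$exclusion_reason == "none"))
  expect_equal(joined$continuous_user, joined$group == "continuous")

  one <- build_cohort(ds$users[1, ], post[post$user_id == ds$users$user_id[1], ],
                      ds$hba1c[ds$hba1c$user_id == ds$users$user_id[1], ],
                      ds$diagnoses[ds$diagnoses$user_id == ds$users$user_id[1], ])
  check_flow(one$flow)
  expect_equal(one$flow$n_accounts, 1)

  empty <- build_cohort(ds$users[0, ], post[0, ], ds$hba1c[0, ],
                        ds$diagnoses[0, ])
  check_flow(empty$flow)
  expect_equal(empty$flow$n_accounts, 0)
})

test_that("exclusion reasons are assigned exactly once and correctly", {
  users <- tibble::tibble(
    user_id = c("A", "B", "C"),
    account_creation_date = as.Date(c("2016-06-01", "2016-06-01",
                                      "2016-06-01")),
    age = c(50, 55, 60), sex = c("male", "female", "male"))
  hba1c <- tibble::tibble(
    user_id = c("A", "A", "B", "C", "C"),
    measure_date = as.Date(c("2016-01-01", "2017-01-01",  # A: fine span
                             "2016-06-01",                # B: one result
                             "2016-01-01", "2017-01-01")),
    value = c(7.5, 7.0, 8.0, 6.0, 6.2))                   # C: below cutoff
  dx <- tibble::tibble(user_id = "A", icd10_code = "E119",
                       diagnosis_date = as.Date("2016-01-01"))
  built <- build_cohort(users, tibble::tibble(
    user_id = character(), `function` = character(),
    event_date = as.Date(character())), hba1c, dx)
  reasons <- setNames(built$cohort$exclusion_reason, built$cohort$user_id)
  expect_equal(reasons[["A"]], "none")
  expect_equal(reasons[["B"]], "inappropriate_measurement")
  expect_equal(reasons[["C"]], "no_diabetes")
  expect_false(built$cohort$continuous_user[built$cohort$user_id == "A"])
  expect_true(is.na(built$cohort$continuous_user[built$cohort$user_id == "B"]))
})
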