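test_that("the D'Agostino implementation matches the frozen SciPy oracle", {
  res <- dagostino_test(oracle_normal60)
  expect_equal(res$statistic, 0.1181684915, tolerance = 1e-8)
  expect_equal(res$p_value, 0.9426273534, tolerance = 1e-8)
  expect_equal(res$z_skew, -0.2599993386, tolerance = 1e-8)
  expect_equal(res$z_kurtosis, 0.2248751553, tolerance = 1e-8)
  res2 <- dagostino_test(oracle_exp80)
  expect_equal(res2$statistic, 51.7975309, tolerance = 1e-7)
  expect_error(dagostino_test(rnorm(5)), class = "phr_argument_error")
})

test_that("the combined normality verdict is calibrated", {
  withr::local_seed(8)
  verdict_normal <- replicate(300, check_normality(rnorm(500))$normal)
  expect_gte(mean(verdict_normal), 0.9)
  verdict_exp <- replicate(100, check_normality(rexp(500))$normal)
  expect_equal(mean(verdict_exp), 0)
  expect_warning(res <- check_normality(rep(7, 30)), "constant")
  expect_false(res$normal)
  expect_error(check_normality(c(1, 2)), class = "phr_argument_error")
  # large-n path (order-statistic thinning for Shapiro-Wilk)
  big <- check_normality(rnorm(8000))
  expect_type(big$shapiro$p_value, "double")
})

test_that("the pooled z test matches the closed form and the chi-square", {
  # printed counts of the regulation table: 38/133 vs 564/7320
  z <- two_prop_z(38, 133, 564, 7320)
  p1 <- 38 / 133; p2 <- 564 / 7320; pp <- (38 + 564) / (133 + 7320)
  z_hand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 133 + 1 / 7320))
  expect_equal(z$statistic, z_hand)
  expect_equal(round(z$statistic, 2), 8.75)
  # z^2 equals Pearson chi-square without continuity correction
  tab <- rbind(c(38, 133 - 38), c(564, 7320 - 564))
  chi <- chisq.test(tab, correct = FALSE)
  expect_equal(z$statistic^2, unname(chi$statistic))
  expect_equal(z$p_value, chi$p.value, tolerance = 1e-12)
})

test_that("Mood's median test matches a hand-built table", {
  res <- median_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  # all of x at or below the grand median, all of y above: chi-square = 8
  expect_equal(res$statistic, 8)
  expect_equal(res$p_value, pchisq(8, 1, lower.tail = FALSE))
  expect_error(median_test(numeric(), 1:3), class = "phr_argument_error")
})

test_that("group comparisons select tests, flip signs and respect nulls", {
  withr::local_seed(21)
  x <- rnorm(200, 10, 2); y <- rnorm(300, 10.5, 2)
  auto <- compare_groups(x, y, "continuous")
  expect_equal(auto$test, "t")
  skew <- compare_groups(rexp(200), rexp(300), "continuous")
  expect_equal(skew$test, "wilcoxon")

  # label swap flips the signed statistic, preserves the p-value
  a <- compare_groups(x, y, "continuous", test = "t")
  b <- compare_groups(y, x, "continuous", test = "t")
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  az <- compare_groups(x > 10, y > 10, "proportion")
  bz <- compare_groups(y > 10, x > 10, "proportion")
  expect_equal(az$statistic, -bz$statistic)
  expect_equal(az$p_value, bz$p_value)

  # identical groups: null results
  same <- compare_groups(x > 10, x > 10, "proportion")
  expect_equal(same$statistic, 0)
  wnull <- compare_groups(x, x, "continuous", test = "wilcoxon")
  expect_gt(wnull$p_value, 0.99)

  # row order never matters
  shuf <- compare_groups(sample(x), sample(y), "continuous", test = "t")
  expect_equal(shuf$statistic, a$statistic)
})

test_that("categorical comparison drops categories empty in both groups", {
  # score distributions with both groups empty at levels 10, 12, 13
  x <- c(rep(0, 30), rep(1, 20), rep(2, 10), rep(9, 2))
  y <- c(rep(0, 50), rep(1, 30), rep(2, 15), rep(9, 1))
  res <- compare_groups(x, y, "categorical")
  expect_equal(res$df, 3)  # 4 observed levels -> 3 df
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("the unadjusted ANCOVA reproduces the t-test F = t^2 identity", {
  withr::local_seed(5)
  tab <- simulate_analysis_table(60, 90)
  only_group <- fit_ancova(tab, terms = "continuous_use")
  tt <- t.test(decline ~ continuous_use, data = tab, var.equal = TRUE)
  expect_equal(only_group$terms$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(only_group$terms$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("the ANCOVA rejects rank-deficient designs by name", {
  withr::local_seed(6)
  tab <- simulate_analysis_table(50, 50)
  tab$dcsi <- 1
  expect_error(fit_ancova(tab), "dcsi", class = "phr_rank_error")
  tab2 <- simulate_analysis_table(50, 50)
  tab2$sugar_weeks <- 2 * tab2$age
  expect_error(fit_ancova(tab2), class = "phr_rank_error")
})

test_that("the logistic model recovers known effects and flags degeneracy", {
  withr::local_seed(33)
  # zero-effect null: continuous-use coefficient within 3 SE of zero
  est <- z <- numeric(30)
  for (i in 1:30) {
    tab <- simulate_analysis_table(120, 1200, effect = 0)
    fit <- fit_regulation_logistic(tab)
    row <- fit$terms[fit$terms$term == "continuous_use", ]
    est[i] <- row$estimate
    z[i] <- row$estimate / row$std_error
  }
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(30))
  expect_lt(mean(abs(z) > 1.96), 0.2)

  # injected +0.6 log-odds on an explicit outcome construction
  withr::local_seed(34)
  est <- numeric(30)
  for (i in 1:30) {
    tab <- simulate_analysis_table(111, 2000)
    tab$first_value <- pmax(tab$first_value, 6.5)
    eta <- -1 + 0.6 * tab$continuous_use - 0.1 * (tab$first_hba1c - 7.5)
    success <- rbinom(nrow(tab), 1, 1 / (1 + exp(-eta)))
    tab$last_value <- ifelse(success == 1, 6.0, 7.0)
    fit <- fit_regulation_logistic(tab)
    est[i] <- fit$terms$estimate[fit$terms$term == "continuous_use"]
  }
  expect_lt(abs(mean(est) - 0.6), 3 * sd(est) / sqrt(30))

  # constant outcome
  tab <- simulate_analysis_table(50, 200)
  tab$first_value <- 7.0
  tab$last_value <- 7.5
  expect_error(fit_regulation_logistic(tab), class = "phr_degenerate_error")

  # complete separation: outcome identical to the group indicator
  tab <- simulate_analysis_table(50, 200)
  tab$first_value <- 7.0
  tab$last_value <- ifelse(tab$continuous_use == 1, 6.0, 7.5)
  expect_error(suppressWarnings(fit_regulation_logistic(tab)),
               class = "phr_separation_error")
})
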