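# Group comparisons and covariate adjustment.
#
# Test conventions, all two-sided:
#   * Student t: pooled variance (classical two-sample t).
#   * Wilcoxon rank-sum: normal approximation with tie correction, no
#     continuity correction (group sizes in the thousands make exact
#     enumeration pointless).
#   * Two-proportion z: pooled variance, no continuity correction, so that
#     z^2 equals the Pearson chi-square on the same 2x2 table.
#   * Mood's median test: 2xk chi-square of counts above vs at-or-below the
#     pooled median (ties counted "below").
#   * ANCOVA: linear model of decline on the group indicator plus the seven
#     confounders; per-term Type II F tests (1 numerator df each; with no
#     interactions these are the drop-one F tests).
#   * Logistic: ML fit with intercept; coding continuous = 1, male = 1.
# No multiple-testing correction is applied (none was used in the source
# analyses); compare_groups() exposes an optional Benjamini-Hochberg
# adjustment helper for users who want one.

ancova_terms <- c("continuous_use", "age", "sex", "first_hba1c", "dcsi",
                  "sugar_weeks", "weeks_before_start", "sugar_count")

#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the skewness and kurtosis z statistics
#' (K2 = Zs^2 + Zk^2, chi-square with 2 df under normality). Requires
#' n >= 8 for the kurtosis approximation to be valid.
#'
#' @param x numeric vector, n >= 8.
#' @return `list(statistic, p_value, z_skew, z_kurtosis)`.
#' @export
dagostino_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino test needs n >= 8.", class = "phr_argument_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort("constant vector.", class = "phr_degenerate_error")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness z (D'Agostino 1970, Johnson SU transform)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurtosis = z_kurt)
}

#' Normality check combining Shapiro-Wilk and D'Agostino K-squared
#'
#' The verdict is "normal" at level `alpha` only when every applicable test
#' is non-significant. Below n = 8 only Shapiro-Wilk is run (the kurtosis
#' approximation is invalid). Shapiro-Wilk is limited to 5000 observations;
#' larger samples are represented by 5000 evenly spaced order statistics (a
#' deterministic thinning that preserves the empirical distribution shape).
#' A constant vector is degenerate: verdict non-normal, with a warning.
#'
#' @param x numeric vector, n >= 3.
#' @param alpha significance level for the verdict (default 0.05).
#' @return `list(normal, shapiro = list(statistic, p_value), dagostino =
#'   list(...) or NULL, n, degenerate)`.
#' @export
check_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) abort("normality check needs n >= 3.", class = "phr_argument_error")
  if (length(unique(x)) == 1) {
    warn("constant vector: normality verdict is degenerate non-normal.")
    return(list(normal = FALSE, shapiro = NULL, dagostino = NULL,
                n = n, degenerate = TRUE))
  }
  xs <- if (n > 5000) {
    sort(x)[unique(round(seq(1, n, length.out = 5000)))]
  } else x
  sw <- shapiro.test(xs)
  dago <- if (n >= 8) dagostino_test(x) else NULL
  normal <- sw$p.value > alpha && (is.null(dago) || dago$p_value > alpha)
  list(normal = normal,
       shapiro = list(statistic = unname(sw$statistic),
                      p_value = sw$p.value),
       dagostino = dago, n = n, degenerate = FALSE)
}

#' Pooled two-proportion z test
#'
#' No continuity correction, pooled variance, two-sided: on a 2x2 table the
#' squared statistic equals the Pearson chi-square.
#'
#' @param x1,n1 successes and size in group 1.
#' @param x2,n2 successes and size in group 2.
#' @return `list(statistic = z, p_value, p1, p2)`.
#' @export
two_prop_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) abort("group sizes must be positive.",
                                class = "phr_argument_error")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(statistic = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Mood's median test for two groups
#'
#' Chi-square (no continuity correction) on the 2x2 table of counts strictly
#' above vs at-or-below the pooled median.
#'
#' @param x,y numeric samples.
#' @return `list(statistic, p_value, grand_median)`.
#' @export
median_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty.", class = "phr_argument_error")
  }
  med <- median(c(x, y))
  tab <- rbind(c(sum(x > med), sum(x <= med)),
               c(sum(y > med), sum(y <= med)))
  if (any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1, grand_median = med))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       grand_median = med)
}

#' Compare one variable between the two engagement groups
#'
#' For `type = "continuous"`, a pooled-variance Student t test when both
#' groups pass [check_normality()], otherwise a Wilcoxon rank-sum test
#' (normal approximation, tie-corrected); override with `test`. For
#' `type = "proportion"` (`x`, `y` logical or 0/1), the pooled two-proportion
#' z test. For `type = "categorical"` (`x`, `y` category labels), a
#' chi-square over the category distribution after dropping categories empty
#' in both groups; an expected cell below 1 sets `low_expected = TRUE`.
#'
#' @param x,y the variable in the continuous and noncontinuous group.
#' @param type the variable's scale.
#' @param test optional override: `"t"`, `"wilcoxon"`, `"median"`,
#'   `"z_proportion"` or `"chi_square"`.
#' @param variable label carried into the result.
#' @return a one-row tibble (`variable`, `test`, group summaries,
#'   `statistic`, `p_value`, `df`, `low_expected`).
#' @export
compare_groups <- function(x, y,
                           type = c("continuous", "proportion", "categorical"),
                           test = NULL, variable = "") {
  type <- match.arg(type)
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty.", class = "phr_argument_error")
  }
  low_expected <- FALSE
  df <- NA_real_
  if (type == "continuous") {
    if (is.null(test)) {
      test <- if (length(x) >= 3 && length(y) >= 3 &&
                  check_normality(x)$normal && check_normality(y)$normal) {
        "t"
      } else "wilcoxon"
    }
    if (test == "t") {
      tt <- t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
    } else if (test == "wilcoxon") {
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
      stat <- unname(wt$statistic); p <- wt$p.value
    } else if (test == "median") {
      mt <- median_test(x, y)
      stat <- mt$statistic; p <- mt$p_value; df <- 1
    } else {
      abort(sprintf("unsupported test '%s' for a continuous variable.", test),
            class = "phr_argument_error")
    }
    g1 <- sprintf("%.4g (%.4g)", mean(x), sd(x))
    g2 <- sprintf("%.4g (%.4g)", mean(y), sd(y))
  } else if (type == "proportion") {
    test <- test %||% "z_proportion"
    zt <- two_prop_z(sum(x), length(x), sum(y), length(y))
    stat <- zt$statistic; p <- zt$p_value
    g1 <- sprintf("%d/%d (%.2f%%)", sum(x), length(x), 100 * zt$p1)
    g2 <- sprintf("%d/%d (%.2f%%)", sum(y), length(y), 100 * zt$p2)
  } else {
    test <- test %||% "chi_square"
    lev <- sort(unique(c(x, y)))
    tab <- rbind(table(factor(x, levels = lev)),
                 table(factor(y, levels = lev)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      stat <- 0; p <- 1; df <- 0
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      low_expected <- any(ct$expected < 1)
      stat <- unname(ct$statistic); p <- ct$p.value
      df <- unname(ct$parameter)
    }
    g1 <- sprintf("n=%d over %d categories", length(x), ncol(tab))
    g2 <- sprintf("n=%d over %d categories", length(y), ncol(tab))
  }
  tibble::tibble(variable = variable, test = test,
                 continuous = g1, noncontinuous = g2,
                 statistic = stat, p_value = p, df = df,
                 low_expected = low_expected)
}

check_analysis_table <- function(data, outcome, terms = ancova_terms) {
  need <- c(outcome, terms)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("analysis table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "phr_argument_error")
  }
  keep <- complete.cases(data[, need])
  data <- data[keep, , drop = FALSE]
  constant <- terms[vapply(terms, function(v) {
    length(unique(data[[v]])) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    abort(sprintf("rank-deficient design: constant covariate(s): %s",
                  paste(constant, collapse = ", ")),
          class = "phr_rank_error")
  }
  data
}

#' ANCOVA of decline on continuous use and the seven confounders
#'
#' Linear model `decline ~ continuous_use + age + sex + first_hba1c + dcsi +
#' sugar_weeks + weeks_before_start + sugar_count` with per-term Type II F
#' tests (each with 1 numerator degree of freedom; equal to the drop-one F
#' since the model has no interactions). Coding: continuous_use 1 =
#' continuous, sex 1 = male.
#'
#' @param data per-user tibble with the `decline` outcome and the eight
#'   covariate columns (`continuous_use` and `sex` logical or 0/1).
#' @param terms model terms; the canonical adjusted analysis always uses all
#'   eight (the default) -- a subset is only useful for diagnostics such as
#'   checking the unadjusted F = t-squared identity.
#' @return `list(model = "ancova", terms = tibble(term, estimate, f, df_num,
#'   df_den, p_value), n_used, ss_type = "II", fit = the lm object)`.
#' @export
fit_ancova <- function(data, terms = ancova_terms) {
  data <- check_analysis_table(data, "decline", terms)
  if (sum(data$continuous_use == 1) < 2 || sum(data$continuous_use == 0) < 2) {
    abort("need at least 2 users per engagement group.",
          class = "phr_argument_error")
  }
  data$continuous_use <- as.numeric(data$continuous_use)
  if ("sex" %in% terms) data$sex <- as.numeric(data$sex)
  fml <- stats::reformulate(terms, response = "decline")
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    abort(sprintf("rank-deficient design: collinear term(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "phr_rank_error")
  }
  dr <- drop1(fit, test = "F")
  terms <- tibble::tibble(
    term = rownames(dr)[-1],
    estimate = unname(coef(fit)[rownames(dr)[-1]]),
    f = dr$`F value`[-1],
    df_num = dr$Df[-1],
    df_den = fit$df.residual,
    p_value = dr$`Pr(>F)`[-1])
  list(model = "ancova", terms = terms, n_used = nrow(data),
       ss_type = "II", fit = fit)
}

#' Logistic regression of glycemic regulation on continuous use
#'
#' For the subset of users with a first HbA1c at or above the threshold, a
#' maximum-likelihood logistic model of the success outcome (last HbA1c
#' below the threshold) on the same eight covariates as the ANCOVA.
#' Coding: continuous = 1, male = 1, outcome regulated = 1.
#'
#' @param data per-user tibble with `first_value`, `last_value` and the
#'   eight covariate columns.
#' @param threshold regulation threshold, % (default 6.5).
#' @return `list(model = "logistic", terms = tibble(term, estimate,
#'   std_error, z, p_value) including the intercept, n_used, fit)`.
#' @export
fit_regulation_logistic <- function(data, threshold = 6.5) {
  if (!all(c("first_value", "last_value") %in% names(data))) {
    abort("`data` needs first_value and last_value columns.",
          class = "phr_argument_error")
  }
  sub <- data[data$first_value >= threshold, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("no users with a high first measurement.",
          class = "phr_argument_error")
  }
  sub$regulated <- as.numeric(sub$last_value < threshold)
  if (length(unique(sub$regulated)) < 2) {
    abort("outcome is constant in the high-first-measurement subset.",
          class = "phr_degenerate_error")
  }
  sub <- check_analysis_table(sub, "regulated")
  sub$continuous_use <- as.numeric(sub$continuous_use)
  sub$sex <- as.numeric(sub$sex)
  fml <- stats::reformulate(ancova_terms, response = "regulated")
  fit <- suppressWarnings(glm(fml, data = sub, family = binomial()))
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10) && any(abs(coef(fit)) > 15)) {
    # separation usually also presents as IWLS non-convergence: test it first
    abort("complete or quasi-complete separation detected (fitted probabilities at 0/1).",
          class = "phr_separation_error")
  }
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge in %d IWLS iterations.",
                  fit$iter),
          class = "phr_convergence_error")
  }
  sm <- summary(fit)$coefficients
  terms <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                          std_error = sm[, 2], z = sm[, 3], p_value = sm[, 4])
  list(model = "logistic", terms = terms, n_used = nrow(sub), fit = fit)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Off by default everywhere (the source analyses applied no correction);
#' provided for users who want FDR-adjusted p-values on a set of
#' comparisons.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Simulate a ready-made analysis table for model calibration
#'
#' Draws the per-user covariate-plus-decline table directly from the
#' generator's covariate model (skipping trajectory and log-event synthesis),
#' for type-I-error and power studies of the adjusted models. Both groups
#' share the reference (noncontinuous) covariate distributions; `effect` is
#' the decline shift added to continuous users (0 = null).
#'
#' @param n_continuous,n_noncontinuous group sizes.
#' @param effect group effect on decline (default 0).
#' @param params reference [group_params()]; default the noncontinuous block.
#' @param decline_cor as in [generator_config()].
#' @return tibble with `decline`, `first_value`, `last_value` and the eight
#'   covariates.
#' @export
simulate_analysis_table <- function(n_continuous, n_noncontinuous,
                                    effect = 0, params = NULL,
                                    decline_cor = c(first_hba1c = -0.54,
                                                    days_before_start = 0.14,
                                                    age = 0.03)) {
  p <- params %||% generator_config()$noncontinuous
  n <- n_continuous + n_noncontinuous
  grp <- c(rep(1, n_continuous), rep(0, n_noncontinuous))
  age <- rnorm_trunc(n, p$age_mean, p$age_sd, 18, Inf)
  sex <- as.numeric(runif(n) < p$male_prop)
  first <- rnorm_trunc(n, p$first_hba1c_mean, p$first_hba1c_sd, 4, 16)
  dbs <- rnorm_trunc(n, p$days_before_start_mean, p$days_before_start_sd,
                     0, Inf)
  dcsi <- pmin(rpois(n, 1.15), 13)
  # engagement covariates drawn from one shared (reference) distribution for
  # both groups: the harness isolates the injected group effect, so the group
  # indicator must not be confounded with, or collinear to, any covariate
  emitter <- rbinom(n, 1, max(p$sugar_user_prob, 0.05))
  sugar_count <- emitter * (1 + rpois(n, p$burst_count_lambda))
  sugar_weeks <- ifelse(sugar_count >= 2, runif(n, 0, 13 / 7), 0)
  z <- cbind(first_hba1c = (first - p$first_hba1c_mean) / p$first_hba1c_sd,
             days_before_start =
               (dbs - p$days_before_start_mean) / p$days_before_start_sd,
             age = (age - p$age_mean) / p$age_sd)
  resid_scale <- sqrt(1 - sum(decline_cor^2))
  decline <- p$decline_mean + effect * grp + p$decline_sd *
    (as.vector(z %*% decline_cor[colnames(z)]) + resid_scale * rnorm(n))
  # a crude last value consistent with the decline (for the logistic model)
  last <- pmin(pmax(first + 100 * decline + rnorm(n, 0, p$hba1c_noise_sd),
                    4), 16)
  tibble::tibble(continuous_use = grp, age = age, sex = sex,
                 first_hba1c = first, dcsi = dcsi,
                 sugar_weeks = sugar_weeks,
                 weeks_before_start = dbs / 7,
                 sugar_count = sugar_count,
                 decline = decline, first_value = first, last_value = last)
}
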