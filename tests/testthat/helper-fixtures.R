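# Shared fixtures and independent oracles.

# A small full dataset used by several suites.
small_dataset <- function(n_cont = 25, n_noncont = 100, seed = 404) {
  generate_dataset(generator_config(n_continuous = n_cont,
                                    n_noncontinuous = n_noncont,
                                    seed = seed))
}

# Brute-force OLS oracle: solve the normal equations directly.
ols_oracle <- function(day, value) {
  X <- cbind(1, day - min(day))
  beta <- solve(t(X) %*% X, t(X) %*% value)
  fitted <- X %*% beta
  sstot <- sum((value - mean(value))^2)
  ssres <- sum((value - fitted)^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = if (sstot == 0 || length(value) == 2) 1 else 1 - ssres / sstot)
}

write_csv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Frozen external oracle (SciPy 1.17 stats.normaltest / skewtest /
# kurtosistest) for the D'Agostino implementation: 60 rounded draws from
# N(7.5, 1.2) and 80 from Exp(1), fixed generator.
oracle_normal60 <- c(
  7.866, 6.252, 8.401, 8.629, 5.159, 5.937, 7.653, 7.121, 7.48, 6.476,
  8.555, 8.433, 7.579, 8.853, 8.061, 6.469, 7.943, 6.349, 8.554, 7.44,
  7.278, 6.683, 8.967, 7.315, 6.986, 7.077, 8.139, 7.939, 7.995, 8.017,
  10.07, 7.012, 6.885, 6.523, 8.239, 8.855, 7.363, 6.492, 6.511, 8.281,
  8.392, 8.152, 6.701, 7.779, 7.64, 7.762, 8.546, 7.768, 8.315, 7.581,
  7.847, 8.258, 5.751, 7.116, 6.936, 6.733, 7.17, 9.294, 6.461, 8.662)
oracle_exp80 <- c(
  1.5078, 5.3099, 2.1067, 1.6449, 1.0435, 0.5925, 0.0445, 0.9566, 0.6214,
  1.508, 2.028, 0.3321, 0.0498, 0.9248, 2.5534, 0.8211, 2.1309, 0.753,
  1.314, 0.2888, 0.1344, 0.1425, 0.1177, 0.0547, 1.7166, 0.4486, 0.3861,
  0.935, 0.1873, 1.9183, 1.292, 0.3292, 0.2006, 0.531, 0.3048, 0.0757,
  0.5036, 2.2519, 1.0088, 3.0824, 2.0464, 1.1179, 1.8506, 0.7269, 1.0678,
  0.3802, 0.2191, 2.1449, 0.1403, 0.1879, 0.3102, 0.9675, 0.4138, 0.6845,
  2.1598, 1.5417, 1.1712, 0.1709, 1.1894, 0.4545, 0.1238, 0.3994, 0.0706,
  0.9151, 0.9717, 0.2943, 0.0458, 2.7293, 0.8078, 1.4881, 0.3528, 1.6764,
  1.6413, 0.0931, 5.4316, 0.6736, 1.3978, 0.2437, 0.9838, 0.2862)
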