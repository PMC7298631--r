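# Shared small helpers: rounding, truncated-normal draws, argument checks.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when recomputing the printed
#' percentages of the study tables. Base R's `round()` rounds half to even,
#' which cannot reproduce printed values such as 82.65 -> 82.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' A percentage from printed counts
#'
#' Computes `100 * numerator / denominator` rounded to the requested number
#' of decimals, the convention used for every percentage in the study report
#' (e.g. 133/7453 -> 1.78). The default is half-up commercial rounding;
#' `rounding = "down"` truncates instead, because published clinical tables
#' mix the two conventions between columns and a reproduction has to be able
#' to match either.
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`.
#' @param decimals decimal places to keep (default 2).
#' @param rounding `"half_up"` (default) or `"down"` (truncation).
#' @return percentage on the 0--100 scale.
#' @export
proportion <- function(numerator, denominator, decimals = 2,
                       rounding = c("half_up", "down")) {
  rounding <- match.arg(rounding)
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "phr_argument_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator].",
          class = "phr_argument_error")
  }
  pct <- 100 * numerator / denominator
  if (rounding == "half_up") {
    round_half_up(pct, decimals)
  } else {
    # tiny epsilon guards exact representable values against FP droop
    floor(pct * 10^decimals + 1e-9) / 10^decimals
  }
}

# Truncated-normal draws by resampling (design choice: re-sample rather than
# clip, so means are not distorted by a point mass at the bound).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf, max_iter = 1000L) {
  if (sd < 0) abort("`sd` must be >= 0.", class = "phr_config_error")
  if (any(lower > upper)) abort("truncation bounds inverted.", class = "phr_argument_error")
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  iter <- 0L
  while (length(bad) > 0 && iter < max_iter) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower[bad] | x[bad] > upper[bad]]
    iter <- iter + 1L
  }
  if (length(bad) > 0) {
    # pathological bounds: fall back to clipping the stragglers
    x[bad] <- pmin(pmax(x[bad], lower[bad]), upper[bad])
  }
  x
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "phr_config_error")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name),
          class = "phr_config_error")
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", name),
          class = "phr_config_error")
  }
  invisible(as.integer(x))
}

# Normalize an ICD-10 code: uppercase, strip the dot. "E11.9" and "E119"
# become the same key. Lexical shape: letter + 2 digits + optional suffix.
normalize_icd10 <- function(code) {
  out <- toupper(gsub(".", "", trimws(as.character(code)), fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", out)
  out[!ok & !is.na(out)] <- NA_character_
  out
}
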