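# Diabetes complications severity index (DCSI) scoring from ICD-10 codes.
#
# Seven complication categories are scored 0/1/2 (neuropathy 0/1) and summed
# to a 0-13 total. Only diagnosis codes are consulted: the laboratory-based
# (urinalysis) severity criteria of the original index are deliberately out
# of scope, mirroring the study setting in which urine laboratory data were
# unavailable. The code-to-category table ships as an editable CSV asset --
# a reconstruction in the spirit of the published claims-data adaptation of
# the index, not a verbatim copy -- so sites can substitute a local mapping.

.dcsi_cache <- new.env(parent = emptyenv())

#' The seven DCSI complication categories
#' @return character vector of category names.
#' @export
dcsi_categories <- function() {
  c("retinopathy", "nephropathy", "neuropathy", "cerebrovascular",
    "cardiovascular", "peripheral_vascular", "metabolic")
}

#' Load a DCSI code mapping
#'
#' Reads and validates a CSV with columns `prefix` (ICD-10 code prefix,
#' dotted or undotted), `category` (one of [dcsi_categories()]) and
#' `severity` (1 or 2; neuropathy entries must be 1).
#'
#' @param path CSV file; default is the packaged mapping asset.
#' @return a tibble with columns `code` (dotted prefix as shipped), `prefix`
#'   (normalized, undotted), `category`, `severity`.
#' @export
dcsi_load_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dcsi_mapping_default.csv",
                                package = "phrglycemia", mustWork = TRUE)
  m <- readr::read_csv(path, col_types = readr::cols(
    prefix = readr::col_character(),
    category = readr::col_character(),
    severity = readr::col_integer()))
  if (!all(m$category %in% dcsi_categories())) {
    abort("mapping contains unknown complication categories.",
          class = "phr_config_error")
  }
  if (!all(m$severity %in% c(1L, 2L))) {
    abort("mapping severities must be 1 or 2.", class = "phr_config_error")
  }
  if (any(m$severity[m$category == "neuropathy"] != 1L)) {
    abort("neuropathy entries must have severity 1.",
          class = "phr_config_error")
  }
  norm <- normalize_icd10(m$prefix)
  if (anyNA(norm)) {
    abort("mapping contains prefixes that are not valid ICD-10 roots.",
          class = "phr_config_error")
  }
  tibble::tibble(code = m$prefix, prefix = norm,
                 category = m$category, severity = m$severity)
}

dcsi_default_mapping <- function() {
  if (is.null(.dcsi_cache$mapping)) {
    .dcsi_cache$mapping <- dcsi_load_mapping()
  }
  .dcsi_cache$mapping
}

#' Map one ICD-10 code to a DCSI category and severity
#'
#' Longest-prefix match: when both a 3-character and a longer prefix match,
#' the longer (more specific) entry wins.
#'
#' @param icd10_code a single ICD-10 code (dotted or undotted).
#' @param mapping a mapping from [dcsi_load_mapping()]; default asset if
#'   omitted.
#' @return `list(category =, severity =)` or `NULL` when no prefix matches.
#' @export
map_code <- function(icd10_code, mapping = NULL) {
  mapping <- mapping %||% dcsi_default_mapping()
  code <- normalize_icd10(icd10_code)
  if (length(code) != 1 || is.na(code)) {
    abort("`icd10_code` must be a single well-formed ICD-10 code.",
          class = "phr_argument_error")
  }
  hit <- startsWith(code, mapping$prefix)
  if (!any(hit)) return(NULL)
  best <- which(hit)[which.max(nchar(mapping$prefix[hit]))]
  list(category = mapping$category[best], severity = mapping$severity[best])
}

#' Score the DCSI for one user
#'
#' Per category the score is the maximum severity among the user's matched
#' codes (0 when none match); the total is the sum over the seven categories,
#' bounded by 13 (six categories scored up to 2 plus neuropathy scored up
#' to 1). Order- and duplicate-invariant; diagnosis codes that map to no
#' category are ignored.
#'
#' @param codes character vector of the user's ICD-10 diagnosis codes.
#' @param mapping a mapping tibble; default asset if omitted.
#' @return a one-row tibble with one `<category>` column per category, the
#'   `total`, and presence flags `<category>_present`.
#' @export
score_user <- function(codes, mapping = NULL) {
  mapping <- mapping %||% dcsi_default_mapping()
  cats <- dcsi_categories()
  score <- setNames(integer(length(cats)), cats)
  codes <- unique(normalize_icd10(codes))
  codes <- codes[!is.na(codes)]
  for (code in codes) {
    hit <- startsWith(code, mapping$prefix)
    if (!any(hit)) next
    best <- which(hit)[which.max(nchar(mapping$prefix[hit]))]
    cat <- mapping$category[best]
    score[cat] <- max(score[cat], mapping$severity[best])
  }
  out <- tibble::as_tibble(as.list(score))
  out$total <- sum(score)
  for (cat in cats) out[[paste0(cat, "_present")]] <- score[[cat]] > 0L
  out
}

#' Score the DCSI for every user in a diagnosis table
#'
#' @param diagnoses tibble with columns `user_id`, `icd10_code` (and
#'   optionally `diagnosis_date`, unused: all available diagnoses count).
#' @param user_ids optional vector of users to score; users without any
#'   diagnosis receive a zero score.
#' @param mapping a mapping tibble; default asset if omitted.
#' @return tibble with `user_id`, per-category scores, `total` and presence
#'   flags.
#' @export
score_dcsi <- function(diagnoses, user_ids = NULL, mapping = NULL) {
  mapping <- mapping %||% dcsi_default_mapping()
  user_ids <- user_ids %||% unique(diagnoses$user_id)
  cats <- dcsi_categories()
  # map each distinct code once, then aggregate max severity per user/category
  codes <- unique(normalize_icd10(diagnoses$icd10_code))
  codes <- codes[!is.na(codes)]
  lut <- purrr::map(codes, function(code) {
    hit <- startsWith(code, mapping$prefix)
    if (!any(hit)) return(NULL)
    best <- which(hit)[which.max(nchar(mapping$prefix[hit]))]
    list(code = code, category = mapping$category[best],
         severity = mapping$severity[best])
  })
  lut <- purrr::list_rbind(purrr::map(purrr::compact(lut), tibble::as_tibble))
  score <- matrix(0L, nrow = length(user_ids), ncol = length(cats),
                  dimnames = list(user_ids, cats))
  if (nrow(diagnoses) > 0 && !is.null(lut) && nrow(lut) > 0) {
    hits <- dplyr::inner_join(
      tibble::tibble(user_id = diagnoses$user_id,
                     code = normalize_icd10(diagnoses$icd10_code)),
      lut, by = "code")
    hits <- hits[hits$user_id %in% user_ids, , drop = FALSE]
    if (nrow(hits) > 0) {
      agg <- dplyr::summarise(
        dplyr::group_by(hits, .data$user_id, .data$category),
        severity = max(.data$severity), .groups = "drop")
      score[cbind(match(agg$user_id, user_ids),
                  match(agg$category, cats))] <- agg$severity
    }
  }
  out <- tibble::as_tibble(as.data.frame(score))
  out <- dplyr::mutate(out, user_id = as.character(user_ids), .before = 1)
  out$total <- as.integer(rowSums(score))
  for (cat in cats) out[[paste0(cat, "_present")]] <- score[, cat] > 0L
  out
}
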