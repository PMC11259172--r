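#' Catalogue of survey items
#'
#' The eight outcomes analyzed along the urban gradient: two well-being
#' items, three social items, three economic items. Six are 6-point Likert
#' scales, loneliness is binary, household income comes in five bands.
#' Higher coded values are the healthy direction for every item except
#' loneliness (1 = often lonely).
#'
#' @return Data frame with `item`, `domain`, `response_type`,
#'   `healthy_direction`.
#' @export
item_specs <- function() {
  data.frame(
    item = c("happiness", "meaningful_life",
             "family_satisfaction", "friendship_satisfaction", "loneliness",
             "income", "financial_satisfaction", "job_satisfaction"),
    domain = c("wellbeing", "wellbeing",
               "social", "social", "social",
               "economic", "economic", "economic"),
    response_type = c("likert6", "likert6",
                      "likert6", "likert6", "binary",
                      "income_bands", "likert6", "likert6"),
    healthy_direction = c("higher", "higher",
                          "higher", "higher", "lower",
                          "higher", "higher", "higher"),
    stringsAsFactors = FALSE
  )
}

#' Special response codes
#'
#' Integer codes used in cohort tables for non-substantive responses.
#' Configurable so external extracts with other conventions can be mapped.
#'
#' @param missing,dontknow,jobless The three codes.
#' @return Named list of codes.
#' @export
special_codes <- function(missing = -3L, dontknow = -1L, jobless = -2L) {
  list(missing = missing, dontknow = dontknow, jobless = jobless)
}

#' Recode household income bands to representative pounds
#'
#' Five pre-tax household income bands are recoded to single representative
#' values: below 18k -> 15,000; 18k-31k -> 25,000; 31k-51k -> 40,000;
#' 51k-100k -> 75,000; above 100k -> 130,000.
#'
#' @param band Integer band(s) in 1..5.
#' @return Pounds.
#' @export
recode_income <- function(band) {
  map <- c(15000, 25000, 40000, 75000, 130000)
  if (any(!band %in% 1:5)) {
    stop("income band outside 1..5", call. = FALSE)
  }
  map[band]
}

#' Drop non-substantive responses for one item
#'
#' Removes rows carrying any special code, with per-category counts logged:
#' `missing` everywhere; `jobless` (relevant to job satisfaction, where the
#' jobless are filtered out); `dontknow` (relevant to meaningful life, where
#' do-not-know responses are discarded).
#'
#' @param raw Data frame holding at least the `value` column for the item.
#' @param item Item name (bookkeeping only).
#' @param codes Special codes, see [special_codes()].
#' @param value_col Name of the response column. Default `"value"`.
#' @return The filtered data frame; attribute `"counts"` holds named counts
#'   `kept`, `missing`, `dontknow`, `jobless`.
#' @export
filter_responses <- function(raw, item, codes = special_codes(),
                             value_col = "value") {
  v <- raw[[value_col]]
  if (is.null(v)) stop("no column '", value_col, "' in raw", call. = FALSE)
  is_missing <- is.na(v) | v == codes$missing
  is_dk <- !is_missing & v == codes$dontknow
  is_jl <- !is_missing & !is_dk & v == codes$jobless
  keep <- !(is_missing | is_dk | is_jl)
  out <- raw[keep, , drop = FALSE]
  attr(out, "counts") <- c(kept = sum(keep), missing = sum(is_missing),
                           dontknow = sum(is_dk), jobless = sum(is_jl))
  attr(out, "item") <- item
  if (!nrow(out)) warning("all responses for '", item, "' were filtered out")
  out
}

#' Standardize values to z-scores
#'
#' Centers and scales with the sample SD (n-1 denominator), so effect sizes
#' along the gradient read directly as Cohen's d. The raw mean and SD are
#' retained for exact inversion.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List of class `standardized_outcome`: `z` (mean 0, SD 1),
#'   `raw_mean`, `raw_sd`, `n_used`.
#' @export
zscore <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L) {
    stop("degenerate variance: need at least 2 distinct values", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(z = (values - m) / s, raw_mean = m, raw_sd = s,
         n_used = length(values)),
    class = "standardized_outcome"
  )
}

#' Estimation and reporting range masks
#'
#' Models are estimated on participants with adjusted distance d < 0.07 (to
#' stabilize the curve at the reporting edge) and reported on d < 0.05
#' (beyond which data are sparse). Both bounds are strict.
#'
#' @param d Vector of adjusted distances.
#' @param estimation_max,reporting_max Strict upper bounds; defaults 0.07
#'   and 0.05.
#' @return List with logical masks `estimation` and `reporting` and the two
#'   bounds.
#' @export
range_masks <- function(d, estimation_max = 0.07, reporting_max = 0.05) {
  stopifnot(reporting_max <= estimation_max)
  list(
    estimation = d < estimation_max,
    reporting = d < reporting_max,
    estimation_max = estimation_max,
    reporting_max = reporting_max
  )
}
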