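#' Modified Index of Caring Dependence (mICD)
#'
#' The mICD rates a patient's dependence on nursing care over eight care
#' dimensions — nutrition/hydration, elimination, hygiene/comfort,
#' mobilization, diagnostic procedures, therapeutic procedures, sensory
#' perception and skin integrity — each on an ordinal 1–4 level, so the
#' total lies in 8–32. (The instrument extends the original seven-dimension
#' index with skin integrity.) The total maps to one of three dependence
#' levels; two cutpoint schemes circulate for that mapping and both are
#' supported:
#'
#' * `text_bands` (default): low 8–14, average 15–23, high 24–32. This is
#'   the scheme the complexity matrix ([icc_default_matrix()]) is keyed to.
#' * `table8_bands`: low 8–16, average 17–25, high >= 26.
#'
#' The numeric level per dimension is the input; the clinical anchors that
#' guide the assessor (e.g. "bladder/condom catheter" is elimination
#' level 2) ship as a reference sheet in
#' `system.file("extdata", "micd_rubric_reference.csv", package = "carecomplexity")`
#' but text-to-level mapping is a bedside judgement, not a computation.
#'
#' @param assessments A data frame with one integer 1–4 column per care
#'   dimension (see [micd_dimension_names()]); other columns pass through.
#' @param scheme Cutpoint scheme, `"text_bands"` or `"table8_bands"`.
#' @return `assessments` with added `micd_total` (integer) and `micd_level`
#'   (ordered factor low < average < high).
#' @export
#' @examples
#' a <- tibble::tibble(
#'   nutrition_hydration = 2, elimination = 2, hygiene_comfort = 3,
#'   mobilization = 3, diagnostic_procedures = 2, therapeutic_procedures = 3,
#'   sensory_perception = 2, skin_integrity = 3
#' )
#' score_micd(a)[, c("micd_total", "micd_level")] # 20, average
score_micd <- function(assessments, scheme = c("text_bands", "table8_bands")) {
  scheme <- match.arg(scheme)
  assessments <- tibble::as_tibble(assessments)
  miss <- setdiff(.micd_dimensions, names(assessments))
  if (length(miss) > 0) {
    stop_validation(paste0("assessment is missing care dimension(s): ",
                           paste(miss, collapse = ", ")))
  }
  if (nrow(assessments) == 0) {
    assessments$micd_total <- integer(0)
    assessments$micd_level <- factor(character(0), levels = .micd_levels,
                                     ordered = TRUE)
    return(assessments)
  }
  for (d in .micd_dimensions) {
    v <- assessments[[d]]
    if (anyNA(v) || !is.numeric(v) || any(v != round(v)) || any(v < 1 | v > 4)) {
      stop_validation(sprintf(
        "care dimension '%s' must be an integer level 1-4 (rows %s)",
        d, paste(utils::head(which(is.na(v) | v < 1 | v > 4 | v != round(v)), 5),
                 collapse = ", ")
      ))
    }
  }
  total <- as.integer(Reduce(`+`, lapply(.micd_dimensions,
                                         function(d) assessments[[d]])))
  assessments$micd_total <- total
  assessments$micd_level <- classify_dependence(total, scheme)
  assessments
}

#' Classify an mICD total into a dependence level
#'
#' @param total Integer mICD total(s), 8–32.
#' @inheritParams score_micd
#' @return Ordered factor with levels low < average < high.
#' @export
#' @examples
#' classify_dependence(c(8, 14, 15, 23, 24, 32))
#' classify_dependence(17, scheme = "table8_bands") # average
classify_dependence <- function(total, scheme = c("text_bands", "table8_bands")) {
  scheme <- match.arg(scheme)
  if (anyNA(total) || !is.numeric(total) || any(total != round(total))) {
    stop_range("mICD total must be integer and non-missing")
  }
  if (any(total < 8 | total > 32)) {
    stop_range("mICD total out of range 8-32")
  }
  cuts <- micd_cutpoints(scheme)
  level <- ifelse(total <= cuts["low_max"], "low",
                  ifelse(total <= cuts["average_max"], "average", "high"))
  factor(level, levels = .micd_levels, ordered = TRUE)
}

micd_cutpoints <- function(scheme) {
  switch(scheme,
    text_bands = c(low_max = 14, average_max = 23),
    table8_bands = c(low_max = 16, average_max = 25)
  )
}

# Inclusive total ranges of each dependence level under a scheme; used by
# the synthetic generator to realize dimension levels inside a target band.
micd_level_ranges <- function(scheme = "text_bands") {
  cuts <- micd_cutpoints(scheme)
  list(
    low = c(8, cuts[["low_max"]]),
    average = c(cuts[["low_max"]] + 1, cuts[["average_max"]]),
    high = c(cuts[["average_max"]] + 1, 32)
  )
}
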