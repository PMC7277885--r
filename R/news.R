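#' National Early Warning Score (NEWS) from vital signs
#'
#' The NEWS operationalizes clinical instability as the sum of banded
#' sub-scores over six physiological parameters — respiration rate, oxygen
#' saturation, temperature, systolic blood pressure, heart rate and
#' consciousness (AVPU) — plus a fixed add-on for patients on supplemental
#' oxygen. Each physiological sub-score is 0–3, the oxygen add-on is 0 or 2,
#' so the total lies in 0–20. The total maps to an instability band:
#' stable (0–4), unstable (5–6), critical (>= 7).
#'
#' `score_news()` scores a data frame of observations (one row each) and
#' returns the input with one `score_*` column per component, the total and
#' the band. Values are compared to the band intervals after rounding
#' temperature to 0.1 degC and all other parameters to integers, with
#' intervals closed on their printed endpoints.
#'
#' @param vitals A data frame with columns `respiration_rate` (breaths/min),
#'   `spo2` (percent saturation), `supplemental_oxygen` (logical or 0/1),
#'   `temperature` (degC), `systolic_bp` (mmHg), `heart_rate` (beats/min)
#'   and `avpu` (`"A"`, `"V"`, `"P"`, `"U"`, or the full words).
#' @param bands A band table from [news_default_bands()] or
#'   [read_news_bands()].
#' @param sanity Named list of physiologic sanity ranges, as returned by
#'   [vital_sanity_bounds()]; observations outside them are rejected.
#' @return `vitals` with added integer columns `score_respiration_rate`,
#'   `score_spo2`, `score_supplemental_oxygen`, `score_temperature`,
#'   `score_systolic_bp`, `score_heart_rate`, `score_avpu`, the integer
#'   `news_total` and the factor `news_band`.
#' @export
#' @examples
#' vit <- tibble::tibble(
#'   respiration_rate = 22, spo2 = 95, supplemental_oxygen = FALSE,
#'   temperature = 36.5, systolic_bp = 105, heart_rate = 95, avpu = "A"
#' )
#' score_news(vit)[, c("news_total", "news_band")]
score_news <- function(vitals, bands = news_default_bands(),
                       sanity = vital_sanity_bounds()) {
  vitals <- tibble::as_tibble(vitals)
  numeric_params <- c("respiration_rate", "spo2", "temperature",
                      "systolic_bp", "heart_rate")
  needed <- c(numeric_params, "supplemental_oxygen", "avpu")
  miss <- setdiff(needed, names(vitals))
  if (length(miss) > 0) {
    stop_validation(paste0("vitals are missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  if (nrow(vitals) == 0) {
    out <- vitals
    for (p in c(numeric_params, "supplemental_oxygen", "avpu")) {
      out[[paste0("score_", p)]] <- integer(0)
    }
    out$news_total <- integer(0)
    out$news_band <- factor(character(0), levels = .news_bands, ordered = TRUE)
    return(out)
  }

  for (p in needed) {
    if (anyNA(vitals[[p]])) {
      stop_validation(sprintf("missing value in vitals field '%s' (rows %s)",
                              p, paste(utils::head(which(is.na(vitals[[p]])), 5),
                                       collapse = ", ")))
    }
  }
  for (p in numeric_params) {
    v <- vitals[[p]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop_validation(sprintf("vitals field '%s' must be finite numeric", p))
    }
    lo <- sanity[[p]][1]; hi <- sanity[[p]][2]
    bad <- which(v < lo | v > hi)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "vitals field '%s' outside sanity range [%g, %g] (rows %s)",
        p, lo, hi, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }

  o2 <- vitals$supplemental_oxygen
  if (is.numeric(o2)) {
    if (!all(o2 %in% c(0, 1))) {
      stop_validation("supplemental_oxygen must be logical or 0/1")
    }
    o2 <- o2 == 1
  }
  if (!is.logical(o2) || anyNA(o2)) {
    stop_validation("supplemental_oxygen must be logical or 0/1")
  }
  avpu <- normalize_avpu(vitals$avpu)

  out <- vitals
  out$score_respiration_rate <- band_lookup(round(vitals$respiration_rate),
                                            bands$respiration_rate, "respiration_rate")
  out$score_spo2 <- band_lookup(round(vitals$spo2), bands$spo2, "spo2")
  out$score_temperature <- band_lookup(round_half_up(vitals$temperature, 1),
                                       bands$temperature, "temperature")
  out$score_systolic_bp <- band_lookup(round(vitals$systolic_bp),
                                       bands$systolic_bp, "systolic_bp")
  out$score_heart_rate <- band_lookup(round(vitals$heart_rate),
                                      bands$heart_rate, "heart_rate")
  out$score_supplemental_oxygen <- ifelse(o2, bands$supplemental_oxygen_score, 0L)
  out$score_avpu <- ifelse(avpu == "A", 0L, bands$avpu_not_alert_score)
  out$news_total <- as.integer(
    out$score_respiration_rate + out$score_spo2 + out$score_temperature +
      out$score_systolic_bp + out$score_heart_rate +
      out$score_supplemental_oxygen + out$score_avpu
  )
  out$news_band <- classify_instability(out$news_total, bands)
  out
}

#' Classify a NEWS total into an instability band
#'
#' @param total Integer NEWS total(s), 0–20.
#' @param bands A band table (only its `band_cutpoints` element is used).
#' @return Ordered factor with levels stable < unstable < critical.
#' @export
#' @examples
#' classify_instability(c(0, 4, 5, 6, 7, 20))
classify_instability <- function(total, bands = news_default_bands()) {
  if (anyNA(total) || !is.numeric(total) || any(total != round(total))) {
    stop_range("NEWS total must be integer and non-missing")
  }
  if (any(total < 0 | total > 20)) {
    stop_range("NEWS total out of range 0-20")
  }
  cp <- bands$band_cutpoints
  band <- ifelse(total <= cp$stable_max, "stable",
                 ifelse(total <= cp$unstable_max, "unstable", "critical"))
  factor(band, levels = .news_bands, ordered = TRUE)
}

#' Default and user-supplied NEWS band tables
#'
#' The shipped default is the Royal College of Physicians NEWS (2012)
#' parameter banding. `read_news_bands()` loads an alternative table from a
#' YAML file with the same layout (per-parameter list of
#' `{min, max, score}` intervals, `supplemental_oxygen_score`,
#' `avpu_not_alert_score`, and `band_cutpoints`), validating that each
#' parameter's intervals are disjoint, jointly cover the parameter's sanity
#' range, and that the band cutpoints are strictly increasing.
#'
#' @return A validated band table (a named list).
#' @export
news_default_bands <- function() {
  path <- system.file("extdata", "news_bands_default.yaml",
                      package = "carecomplexity", mustWork = TRUE)
  read_news_bands(path)
}

#' @rdname news_default_bands
#' @param path Path to a YAML band-table file.
#' @param sanity Sanity bounds the intervals must cover.
#' @export
read_news_bands <- function(path, sanity = vital_sanity_bounds()) {
  if (!file.exists(path)) stop_io(paste0("band table file not found: ", path))
  raw <- yaml::read_yaml(path)
  bands <- validate_band_table(raw, sanity)
  bands
}

#' Physiologic sanity bounds for vital signs
#'
#' Observations outside these ranges are treated as data errors, not
#' extreme scores. Override individual entries to localize.
#'
#' @param ... Named overrides, each a length-2 numeric `c(min, max)`.
#' @return Named list of length-2 numeric ranges.
#' @export
#' @examples
#' vital_sanity_bounds(spo2 = c(40, 100))
vital_sanity_bounds <- function(...) {
  defaults <- list(
    respiration_rate = c(0, 80),
    spo2 = c(50, 100),
    temperature = c(25, 45),
    systolic_bp = c(30, 300),
    heart_rate = c(0, 300)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) stop_config(paste0("unknown vital field(s): ",
                                          paste(bad, collapse = ", ")))
  modifyList(defaults, overrides)
}

# -- internal -----------------------------------------------------------

normalize_avpu <- function(x) {
  x <- as.character(x)
  full <- c(alert = "A", verbal = "V", pain = "P", unresponsive = "U")
  lowered <- tolower(x)
  x <- ifelse(lowered %in% names(full), unname(full[lowered]), toupper(x))
  bad <- setdiff(unique(x), .avpu_levels)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "invalid avpu value(s): %s (expected A/V/P/U or Alert/Verbal/Pain/Unresponsive)",
      paste(bad, collapse = ", ")
    ))
  }
  x
}

band_lookup <- function(values, intervals, what) {
  mins <- vapply(intervals, function(iv) iv$min, numeric(1))
  maxs <- vapply(intervals, function(iv) iv$max, numeric(1))
  scores <- vapply(intervals, function(iv) as.integer(iv$score), integer(1))
  vapply(values, function(v) {
    hit <- which(v >= mins & v <= maxs)
    if (length(hit) == 0) {
      stop_validation(sprintf("value %g of '%s' not covered by the band table",
                              v, what))
    }
    scores[hit[1]]
  }, integer(1))
}

validate_band_table <- function(bands, sanity = vital_sanity_bounds()) {
  params <- c("respiration_rate", "spo2", "temperature", "systolic_bp",
              "heart_rate")
  miss <- setdiff(c(params, "supplemental_oxygen_score",
                    "avpu_not_alert_score", "band_cutpoints"), names(bands))
  if (length(miss) > 0) {
    stop_config(paste0("band table is missing element(s): ",
                       paste(miss, collapse = ", ")))
  }
  # the comparison resolution per parameter: printed endpoints are adjacent
  # at this step, so "disjoint + adjacent" means cover without overlap
  step <- c(respiration_rate = 1, spo2 = 1, temperature = 0.1,
            systolic_bp = 1, heart_rate = 1)
  for (p in params) {
    iv <- bands[[p]]
    mins <- vapply(iv, function(x) as.numeric(x$min), numeric(1))
    maxs <- vapply(iv, function(x) as.numeric(x$max), numeric(1))
    scores <- vapply(iv, function(x) as.numeric(x$score), numeric(1))
    ord <- order(mins)
    mins <- mins[ord]; maxs <- maxs[ord]; scores <- scores[ord]
    if (any(maxs < mins)) stop_config(sprintf("band table '%s': empty interval", p))
    if (!all(scores %in% 0:3)) {
      stop_config(sprintf("band table '%s': sub-scores must be in 0-3", p))
    }
    if (length(mins) > 1) {
      gaps <- mins[-1] - maxs[-length(maxs)]
      if (any(abs(gaps - step[[p]]) > 1e-9)) {
        stop_config(sprintf(
          "band table '%s': intervals must be disjoint and adjacent at resolution %g",
          p, step[[p]]
        ))
      }
    }
    if (mins[1] > sanity[[p]][1] || maxs[length(maxs)] < sanity[[p]][2]) {
      stop_config(sprintf("band table '%s': intervals do not cover the sanity range", p))
    }
    bands[[p]] <- lapply(seq_along(mins), function(i) {
      list(min = mins[i], max = maxs[i], score = as.integer(scores[i]))
    })
  }
  o2 <- bands$supplemental_oxygen_score
  if (!is.numeric(o2) || length(o2) != 1 || !o2 %in% c(0, 2)) {
    stop_config("supplemental_oxygen_score must be 0 or 2")
  }
  bands$supplemental_oxygen_score <- as.integer(o2)
  av <- bands$avpu_not_alert_score
  if (!is.numeric(av) || length(av) != 1 || !av %in% 0:3) {
    stop_config("avpu_not_alert_score must be in 0-3")
  }
  bands$avpu_not_alert_score <- as.integer(av)
  cp <- bands$band_cutpoints
  if (is.null(cp$stable_max) || is.null(cp$unstable_max) ||
      !(cp$stable_max < cp$unstable_max)) {
    stop_config("band cutpoints must satisfy stable_max < unstable_max")
  }
  bands
}
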