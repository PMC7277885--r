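#' Apply the study inclusion rules to a cohort
#'
#' Keeps hospitalizations that overlap the analysis window and are true
#' inpatient stays of the analyzed wards: day-hospital and outpatient
#' records are dropped, as are patients transferred in from a hospital ward
#' outside the analyzed area. Each excluded record is counted under the
#' first rule it fails (window, then day-hospital, outpatient, external
#' transfer-in).
#'
#' @param cohort A [care_cohort()].
#' @param window_start,window_end Dates delimiting the analysis window; a
#'   stay overlaps the window when `admission_date <= window_end` and
#'   `discharge_date > window_start`.
#' @return A list with `cohort` (the filtered [care_cohort()]) and
#'   `exclusions`, a named integer vector of per-rule exclusion counts.
#' @export
apply_inclusion_filters <- function(cohort, window_start, window_end) {
  stopifnot(inherits(cohort, "care_cohort"))
  window_start <- as_iso_date(window_start, "window_start")
  window_end <- as_iso_date(window_end, "window_end")
  if (window_end < window_start) {
    stop_validation("window_end must not precede window_start")
  }
  p <- cohort$patients
  exclusions <- c(outside_window = 0L, day_hospital = 0L,
                  outpatient = 0L, external_transfer = 0L)
  if (nrow(p) == 0) {
    return(list(cohort = cohort, exclusions = exclusions))
  }
  in_window <- p$admission_date <= window_end & p$discharge_date > window_start
  day_hosp <- p$admission_type == "day_hospital"
  outpat <- p$admission_type == "outpatient"
  external <- p$admission_source == "external_ward"

  rule <- ifelse(!in_window, "outside_window",
          ifelse(day_hosp, "day_hospital",
          ifelse(outpat, "outpatient",
          ifelse(external, "external_transfer", "keep"))))
  for (r in names(exclusions)) exclusions[[r]] <- sum(rule == r)
  keep_ids <- p$patient_id[rule == "keep"]

  kept <- care_cohort(
    patients = p[p$patient_id %in% keep_ids, , drop = FALSE],
    settings = cohort$settings[cohort$settings$patient_id %in% keep_ids, , drop = FALSE],
    vitals = cohort$vitals[cohort$vitals$patient_id %in% keep_ids, , drop = FALSE],
    assessments = cohort$assessments[cohort$assessments$patient_id %in% keep_ids, , drop = FALSE],
    validate = FALSE
  )
  list(cohort = kept, exclusions = exclusions)
}

#' Expand a cohort into one row per patient-day
#'
#' The "per day" analysis unit: every hospitalization contributes one row
#' per calendar day from admission (inclusive) to discharge (exclusive).
#' Each day carries the care setting of the interval containing it, the
#' daily maximum NEWS total over that day's observations with its
#' instability band, the most recent care-dependence assessment at or
#' before that day with its level, and the resulting complexity class.
#'
#' @param cohort A validated [care_cohort()].
#' @param bands NEWS band table, see [news_default_bands()].
#' @param icc_matrix Complexity matrix, see [icc_default_matrix()].
#' @param scheme mICD cutpoint scheme, see [classify_dependence()].
#' @param missing_vitals `"strict"` errors on any patient-day without a
#'   vital-sign observation; `"carry_forward"` reuses the previous day's
#'   daily maximum within the same stay (retrospective records are often
#'   incomplete) and reports how many days were filled via a message.
#' @return A tibble with columns `patient_id`, `date`, `ward`, `setting`,
#'   `news_total_daily_max`, `news_band`, `micd_total_current`,
#'   `micd_level`, `icc_level`.
#' @export
expand_to_days <- function(cohort, bands = news_default_bands(),
                           icc_matrix = icc_default_matrix(),
                           scheme = c("text_bands", "table8_bands"),
                           missing_vitals = c("strict", "carry_forward")) {
  stopifnot(inherits(cohort, "care_cohort"))
  scheme <- match.arg(scheme)
  missing_vitals <- match.arg(missing_vitals)
  p <- cohort$patients
  if (nrow(p) == 0) {
    return(tibble::tibble(
      patient_id = character(0), date = as.Date(character(0)),
      ward = factor(character(0), levels = .wards),
      setting = factor(character(0), levels = .settings),
      news_total_daily_max = integer(0),
      news_band = factor(character(0), levels = .news_bands, ordered = TRUE),
      micd_total_current = integer(0),
      micd_level = factor(character(0), levels = .micd_levels, ordered = TRUE),
      icc_level = factor(character(0), levels = .icc_levels, ordered = TRUE)
    ))
  }

  days <- p |>
    dplyr::mutate(
      date = purrr::map2(.data$admission_date, .data$discharge_date,
                         function(a, d) seq(a, d - 1, by = "day"))
    ) |>
    dplyr::select("patient_id", "ward", "date") |>
    tidyr::unnest("date")

  # setting of the interval containing each day
  days <- days |>
    dplyr::left_join(cohort$settings, by = "patient_id",
                     relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$start_date, .data$date < .data$end_date) |>
    dplyr::select("patient_id", "ward", "date", "setting")

  # daily maximum NEWS total
  scored_v <- score_news(cohort$vitals, bands = bands)
  daily_max <- scored_v |>
    dplyr::mutate(date = .data$observed_at) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::summarise(news_total_daily_max = max(.data$news_total),
                     .groups = "drop")
  days <- dplyr::left_join(days, daily_max, by = c("patient_id", "date")) |>
    dplyr::arrange(.data$patient_id, .data$date)

  if (anyNA(days$news_total_daily_max)) {
    if (missing_vitals == "strict") {
      miss <- days[is.na(days$news_total_daily_max), c("patient_id", "date")]
      stop_validation(paste0(
        "no vital-sign observation on ", nrow(miss), " patient-day(s), e.g. ",
        paste(utils::head(paste(miss$patient_id, miss$date), 3), collapse = "; "),
        " (use missing_vitals = \"carry_forward\" to fill from the previous day)"
      ))
    }
    n_missing <- sum(is.na(days$news_total_daily_max))
    days <- days |>
      dplyr::group_by(.data$patient_id) |>
      tidyr::fill("news_total_daily_max", .direction = "down") |>
      dplyr::ungroup()
    if (anyNA(days$news_total_daily_max)) {
      miss <- days[is.na(days$news_total_daily_max), c("patient_id", "date")]
      stop_validation(paste0(
        "no vital-sign observation on or before ", nrow(miss),
        " patient-day(s), e.g. ",
        paste(utils::head(paste(miss$patient_id, miss$date), 3), collapse = "; ")
      ))
    }
    message(n_missing, " patient-day(s) without observations filled by carry-forward")
  }
  days$news_total_daily_max <- as.integer(days$news_total_daily_max)
  days$news_band <- classify_instability(days$news_total_daily_max, bands)

  # most recent care-dependence assessment at or before each day
  scored_a <- score_micd(cohort$assessments, scheme = scheme)
  current <- days |>
    dplyr::select("patient_id", "date") |>
    dplyr::left_join(
      scored_a |> dplyr::select("patient_id", "assessed_at", "micd_total"),
      by = "patient_id", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$assessed_at <= .data$date) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::slice_max(.data$assessed_at, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "date", micd_total_current = "micd_total")
  days <- dplyr::left_join(days, current, by = c("patient_id", "date"))
  if (anyNA(days$micd_total_current)) {
    miss <- days[is.na(days$micd_total_current), c("patient_id", "date")]
    stop_validation(paste0(
      "no care-dependence assessment at or before ", nrow(miss),
      " patient-day(s), e.g. ",
      paste(utils::head(paste(miss$patient_id, miss$date), 3), collapse = "; ")
    ))
  }
  days$micd_level <- classify_dependence(days$micd_total_current, scheme)
  days$icc_level <- classify_icc(days$news_band, days$micd_level, icc_matrix)
  days
}

#' Cross-tabulate two factors with row percentages and a chi-square test
#'
#' Builds the contingency table of `row_factor` by `col_factor` over
#' analysis units (patient-days or patients), with row percentages printed
#' to one decimal (rounded half up) and a `Total` margin row expressed as
#' percentages of the grand total — the layout of published
#' setting-by-complexity tables. A Pearson chi-square test of independence
#' (no continuity correction) is attached; rows or columns with zero margin
#' are retained in the counts but dropped from the test, and a warning is
#' recorded when any expected count falls below 5.
#'
#' @param data A data frame of analysis units.
#' @param row_factor,col_factor Column names (strings) of the two factors.
#' @return A `care_crosstab`: list with `counts` (matrix), `row_percent`
#'   (matrix including the `Total` row), `chi2_stat`, `chi2_dof`, `chi2_p`,
#'   `n`, and `expected_warning`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), c(30, 30)),
#'                  h = rep(c("x", "y", "x"), 20))
#' crosstab(df, "g", "h")
crosstab <- function(data, row_factor, col_factor) {
  if (nrow(data) == 0) stop_validation("crosstab on empty input")
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(data)) {
      stop_validation(paste0("factor column not found: ", f))
    }
  }
  counts <- table(data[[row_factor]], data[[col_factor]])
  counts <- unclass(counts)
  names(dimnames(counts)) <- c(row_factor, col_factor)

  n <- sum(counts)
  rs <- rowSums(counts)
  row_percent <- counts
  for (i in seq_len(nrow(counts))) {
    row_percent[i, ] <- if (rs[i] > 0) {
      round_half_up(100 * counts[i, ] / rs[i], 1)
    } else 0
  }
  total_row <- round_half_up(100 * colSums(counts) / n, 1)
  row_percent <- rbind(row_percent, Total = total_row)

  test_tab <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  expected_warning <- FALSE
  if (nrow(test_tab) > 1 && ncol(test_tab) > 1) {
    ch <- suppressWarnings(stats::chisq.test(test_tab, correct = FALSE))
    expected_warning <- any(ch$expected < 5)
    if (expected_warning) {
      warn("chi-square approximation may be poor: expected count below 5",
           class = "carecomplexity_expected_count_warning")
    }
    chi2_stat <- unname(ch$statistic)
    chi2_dof <- unname(ch$parameter)
    chi2_p <- unname(ch$p.value)
  } else {
    chi2_stat <- NA_real_; chi2_dof <- NA_real_; chi2_p <- NA_real_
  }
  structure(
    list(counts = counts, row_percent = row_percent, n = n,
         chi2_stat = chi2_stat, chi2_dof = chi2_dof, chi2_p = chi2_p,
         expected_warning = expected_warning),
    class = "care_crosstab"
  )
}

#' @export
print.care_crosstab <- function(x, ...) {
  cat("<care_crosstab> n =", x$n, "\n")
  disp <- matrix("", nrow = nrow(x$row_percent), ncol = 2 * ncol(x$counts),
                 dimnames = list(
                   rownames(x$row_percent),
                   as.vector(rbind(paste0(colnames(x$counts), " N"),
                                   paste0(colnames(x$counts), " %")))
                 ))
  counts_with_total <- rbind(x$counts, Total = colSums(x$counts))
  for (j in seq_len(ncol(x$counts))) {
    disp[, 2 * j - 1] <- counts_with_total[, j]
    disp[, 2 * j] <- sprintf("%.1f", x$row_percent[, j])
  }
  print(as.data.frame(disp), ...)
  if (!is.na(x$chi2_stat)) {
    cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n",
                x$chi2_stat, as.integer(x$chi2_dof), x$chi2_p))
  }
  invisible(x)
}

#' Expected complexity class per care setting
#'
#' The allocation hypothesis: sub-intensive and high-care beds are meant
#' for High-complexity patients, medium care for Medium, low care for Low.
#' Override to evaluate alternative allocation policies.
#'
#' @return Named character vector mapping each setting to an ICC class.
#' @export
default_setting_expectation <- function() {
  c(sub_intensive = "High", high = "High", medium = "Medium", low = "Low")
}

#' Allocation-consistency analysis over patient-days
#'
#' For each care setting, the proportion of patient-days whose complexity
#' class equals the class the setting is intended for, plus the overall
#' proportion. A high-complexity day spent in low care (the "roof" effect)
#' or a low-complexity day in sub-intensive care (the "floor" effect) both
#' count as inconsistent.
#'
#' @param day_rows Output of [expand_to_days()].
#' @param mapping Named character vector over all four settings, see
#'   [default_setting_expectation()].
#' @return A tibble with columns `setting` (the four settings plus
#'   `"overall"`), `expected_icc`, `n_days`, `n_consistent`, `proportion`.
#' @export
consistency_analysis <- function(day_rows,
                                 mapping = default_setting_expectation()) {
  miss <- setdiff(.settings, names(mapping))
  if (length(miss) > 0) {
    stop_config(paste0("consistency mapping missing setting(s): ",
                       paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(unname(mapping)), .icc_levels)
  if (length(bad) > 0) {
    stop_config(paste0("consistency mapping has invalid ICC class(es): ",
                       paste(bad, collapse = ", ")))
  }
  if (nrow(day_rows) == 0) stop_validation("consistency analysis on empty input")
  expected <- unname(mapping[as.character(day_rows$setting)])
  consistent <- as.character(day_rows$icc_level) == expected
  per_setting <- tibble::tibble(
    setting = .settings,
    expected_icc = unname(mapping[.settings])
  ) |>
    dplyr::left_join(
      tibble::tibble(setting = as.character(day_rows$setting),
                     consistent = consistent) |>
        dplyr::group_by(.data$setting) |>
        dplyr::summarise(n_days = dplyr::n(),
                         n_consistent = sum(.data$consistent),
                         .groups = "drop"),
      by = "setting"
    ) |>
    dplyr::mutate(
      n_days = dplyr::coalesce(.data$n_days, 0L),
      n_consistent = dplyr::coalesce(.data$n_consistent, 0L),
      proportion = ifelse(.data$n_days > 0,
                          .data$n_consistent / .data$n_days, NA_real_)
    )
  overall <- tibble::tibble(
    setting = "overall", expected_icc = NA_character_,
    n_days = nrow(day_rows), n_consistent = sum(consistent),
    proportion = mean(consistent)
  )
  dplyr::bind_rows(per_setting, overall)
}

#' Per-patient summary by admission complexity class
#'
#' The "per patient" validation analysis: patients are classed by the
#' complexity of their admission-day assessment (first NEWS observation of
#' the admission day combined with the admission care-dependence
#' assessment) and compared on external indices — death, transfer to a
#' higher care level, length of stay and DRG economic value.
#'
#' Records lacking an admission-day vital-sign observation or an
#' admission-context dependence assessment are excluded and returned in the
#' `flagged` attribute.
#'
#' @inheritParams expand_to_days
#' @return A tibble with one row per admission ICC class: `admission_icc`,
#'   `n`, `n_death`, `n_transfer_higher`, `mean_los_days`, `mean_drg_value`;
#'   attribute `flagged` lists excluded patient ids.
#' @export
per_patient_summary <- function(cohort, bands = news_default_bands(),
                                icc_matrix = icc_default_matrix(),
                                scheme = c("text_bands", "table8_bands")) {
  stopifnot(inherits(cohort, "care_cohort"))
  scheme <- match.arg(scheme)
  p <- cohort$patients
  if (nrow(p) == 0) stop_validation("per-patient summary on empty cohort")

  scored_v <- score_news(cohort$vitals, bands = bands)
  admission_news <- scored_v |>
    dplyr::inner_join(p |> dplyr::select("patient_id", "admission_date"),
                      by = "patient_id") |>
    dplyr::filter(.data$observed_at == .data$admission_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", admission_news_total = "news_total")

  scored_a <- score_micd(cohort$assessments, scheme = scheme)
  admission_micd <- scored_a |>
    dplyr::filter(.data$context == "admission") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", admission_micd_total = "micd_total")

  joined <- p |>
    dplyr::left_join(admission_news, by = "patient_id") |>
    dplyr::left_join(admission_micd, by = "patient_id")
  flagged <- joined$patient_id[is.na(joined$admission_news_total) |
                                 is.na(joined$admission_micd_total)]
  joined <- joined[!joined$patient_id %in% flagged, , drop = FALSE]
  if (nrow(joined) == 0) {
    stop_validation("no record carries both admission assessments")
  }

  joined$admission_icc <- classify_icc(
    classify_instability(joined$admission_news_total, bands),
    classify_dependence(joined$admission_micd_total, scheme),
    icc_matrix
  )
  joined$los_days <- as.integer(joined$discharge_date - joined$admission_date)
  out <- joined |>
    dplyr::group_by(admission_icc = .data$admission_icc, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_death = sum(.data$outcome == "death"),
      n_transfer_higher = sum(.data$outcome == "transfer_higher_care"),
      mean_los_days = ifelse(dplyr::n() > 0, mean(.data$los_days), NA_real_),
      mean_drg_value = ifelse(dplyr::n() > 0, mean(.data$drg_value), NA_real_),
      .groups = "drop"
    )
  attr(out, "flagged") <- as.character(flagged)
  out
}

#' Normality and rank-based group comparison
#'
#' The comparison battery used on age and other continuous variables
#' across wards or settings: a Shapiro–Wilk normality test per group (the
#' approximation is accurate for group sizes 4–2000; outside that a warning
#' is issued and the statistic still returned where computable) followed by
#' a Kruskal–Wallis H test (one-way ANOVA on ranks, midranks with tie
#' correction).
#'
#' @param values Numeric vector.
#' @param group_labels Vector of group labels, same length as `values`.
#' @return A list with `shapiro` (tibble: `group`, `n`, `w`, `p`),
#'   `kruskal_h`, `kruskal_dof`, `kruskal_p`.
#' @export
#' @examples
#' group_comparison(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                  rep(c("a", "b", "c"), each = 3))$kruskal_h # 7.2
group_comparison <- function(values, group_labels) {
  if (length(values) != length(group_labels)) {
    stop_validation("values and group_labels must have equal length")
  }
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  group_labels <- as.character(group_labels)[keep]
  groups <- unique(group_labels)
  if (length(groups) < 2) {
    stop_validation("group comparison needs at least 2 non-empty groups")
  }
  shapiro <- purrr::map_dfr(groups, function(g) {
    v <- values[group_labels == g]
    n <- length(v)
    if (n < 4 || n > 2000) {
      warn(sprintf(
        "Shapiro-Wilk approximation is accurate for 4 <= n <= 2000; group '%s' has n = %d",
        g, n
      ), class = "carecomplexity_shapiro_n_warning")
    }
    if (n >= 3 && n <= 5000 && length(unique(v)) > 1) {
      sw <- stats::shapiro.test(v)
      tibble::tibble(group = g, n = n, w = unname(sw$statistic),
                     p = unname(sw$p.value))
    } else {
      tibble::tibble(group = g, n = n, w = NA_real_, p = NA_real_)
    }
  })
  kw <- stats::kruskal.test(values, factor(group_labels))
  list(
    shapiro = shapiro,
    kruskal_h = unname(kw$statistic),
    kruskal_dof = unname(kw$parameter),
    kruskal_p = unname(kw$p.value)
  )
}
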