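#' Configuration for the synthetic cohort generator
#'
#' A `cohort_config` fixes every distribution the generator draws from:
#' ward sizes, demographics, length-of-stay (LOS) classes, care-setting
#' allocation, discharge outcomes, and the latent severity model — the
#' per-setting mixes over instability bands and dependence levels that are
#' realized into concrete vitals and dimension levels. All probability
#' rows must sum to 1.
#'
#' @param n_patients Named integer vector of patients per ward (names from
#'   [ward_labels()]).
#' @param total_patient_days Exact cohort total of patient-days, enforced
#'   via [repair_total_days()]; `NULL` leaves sampled LOS untouched.
#' @param gender_probs Ward-by-`c("male","female")` probability matrix.
#' @param age_class_probs Ward-by-age-class probability matrix; classes are
#'   defined by `age_class_bounds`.
#' @param age_class_bounds List of inclusive `c(min, max)` age ranges.
#' @param los_class_probs Ward-by-LOS-class probability matrix.
#' @param los_class_bounds List of inclusive `c(min, max)` day ranges.
#' @param setting_probs Ward-by-setting probability matrix (see
#'   [setting_labels()]); a zero cell forbids that allocation.
#' @param outcome_probs Ward-by-outcome probability matrix (9 outcome
#'   categories).
#' @param news_band_probs Setting-by-band probability matrix: the latent
#'   daily instability mix per setting.
#' @param micd_level_probs Setting-by-level probability matrix: the latent
#'   dependence mix per setting interval.
#' @param mismatch_rate Fraction `m` of patient-days whose setting is
#'   re-assigned, after severity is drawn, to a setting inconsistent with
#'   the day's complexity class (uniformly among inconsistent settings).
#' @param transfer_prob Probability that a stay of two or more days has one
#'   mid-stay setting transfer.
#' @param window_start First admission date.
#' @param admission_spread_days Admissions fall uniformly on
#'   `window_start + 0:(admission_spread_days - 1)`.
#' @param scheme mICD cutpoint scheme used to realize dimension levels.
#' @param bands NEWS band table used to realize vitals.
#' @param icc_matrix Complexity matrix (defines inconsistency for
#'   `mismatch_rate`).
#' @param consistency_mapping Setting-to-expected-class mapping used by the
#'   mismatch mechanism; see [default_setting_expectation()].
#' @param critical_total_range Inclusive range of NEWS totals realized for
#'   critical-band days (ward cohorts rarely exceed the low teens).
#' @param drg_meanlog,drg_sdlog Log-normal parameters of the pass-through
#'   DRG economic value (EUR).
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(
    n_patients = c(internal_medicine = 20, neurology = 5, pneumology = 5),
    total_patient_days = NULL,
    gender_probs = NULL,
    age_class_probs = NULL,
    age_class_bounds = list(c(18, 60), c(61, 70), c(71, 80), c(81, 90), c(91, 100)),
    los_class_probs = NULL,
    los_class_bounds = list(c(1, 3), c(4, 9), c(10, 15), c(16, 30)),
    setting_probs = NULL,
    outcome_probs = NULL,
    news_band_probs = NULL,
    micd_level_probs = NULL,
    mismatch_rate = 0,
    transfer_prob = 0.15,
    window_start = as.Date("2020-01-15"),
    admission_spread_days = 31L,
    scheme = c("text_bands", "table8_bands"),
    bands = news_default_bands(),
    icc_matrix = icc_default_matrix(),
    consistency_mapping = default_setting_expectation(),
    critical_total_range = c(7L, 12L),
    drg_meanlog = 8.2,
    drg_sdlog = 0.5) {
  scheme <- match.arg(scheme)
  uniform_rows <- function(rows, cols) {
    matrix(1 / length(cols), nrow = length(rows), ncol = length(cols),
           dimnames = list(rows, cols))
  }
  gender_probs <- gender_probs %||% uniform_rows(.wards, c("male", "female"))
  age_class_probs <- age_class_probs %||%
    uniform_rows(.wards, paste0("age", seq_along(age_class_bounds)))
  los_class_probs <- los_class_probs %||%
    uniform_rows(.wards, paste0("los", seq_along(los_class_bounds)))
  setting_probs <- setting_probs %||% uniform_rows(.wards, .settings)
  outcome_probs <- outcome_probs %||% uniform_rows(.wards, .outcomes)
  news_band_probs <- news_band_probs %||% uniform_rows(.settings, .news_bands)
  micd_level_probs <- micd_level_probs %||% uniform_rows(.settings, .micd_levels)

  cfg <- structure(list(
    n_patients = n_patients, total_patient_days = total_patient_days,
    gender_probs = gender_probs, age_class_probs = age_class_probs,
    age_class_bounds = age_class_bounds, los_class_probs = los_class_probs,
    los_class_bounds = los_class_bounds, setting_probs = setting_probs,
    outcome_probs = outcome_probs, news_band_probs = news_band_probs,
    micd_level_probs = micd_level_probs, mismatch_rate = mismatch_rate,
    transfer_prob = transfer_prob, window_start = as_iso_date(window_start, "window_start"),
    admission_spread_days = as.integer(admission_spread_days), scheme = scheme,
    bands = bands, icc_matrix = icc_matrix,
    consistency_mapping = consistency_mapping,
    critical_total_range = as.integer(critical_total_range),
    drg_meanlog = drg_meanlog, drg_sdlog = drg_sdlog
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!all(.wards %in% names(cfg$n_patients)) ||
      any(cfg$n_patients < 0) || any(cfg$n_patients != round(cfg$n_patients))) {
    stop_config("n_patients must be a non-negative integer vector named by ward")
  }
  n_total <- sum(cfg$n_patients)
  if (!is.null(cfg$total_patient_days)) {
    if (cfg$total_patient_days < n_total) {
      stop_config(sprintf(
        "infeasible config: total_patient_days (%d) < number of patients (%d)",
        cfg$total_patient_days, n_total
      ))
    }
  }
  check_probs <- function(m, rows, what) {
    if (!all(rows %in% rownames(m))) {
      stop_config(paste0(what, " must have rows ", paste(rows, collapse = ", ")))
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
      stop_config(paste0(what, " rows must be non-negative and sum to 1"))
    }
  }
  check_probs(cfg$gender_probs, .wards, "gender_probs")
  check_probs(cfg$age_class_probs, .wards, "age_class_probs")
  check_probs(cfg$los_class_probs, .wards, "los_class_probs")
  check_probs(cfg$setting_probs, .wards, "setting_probs")
  check_probs(cfg$outcome_probs, .wards, "outcome_probs")
  check_probs(cfg$news_band_probs, .settings, "news_band_probs")
  check_probs(cfg$micd_level_probs, .settings, "micd_level_probs")
  if (cfg$mismatch_rate < 0 || cfg$mismatch_rate > 1) {
    stop_config("mismatch_rate must be in [0, 1]")
  }
  if (cfg$transfer_prob < 0 || cfg$transfer_prob > 1) {
    stop_config("transfer_prob must be in [0, 1]")
  }
  if (length(cfg$age_class_bounds) != ncol(cfg$age_class_probs) ||
      length(cfg$los_class_bounds) != ncol(cfg$los_class_probs)) {
    stop_config("class bounds and class probability columns must align")
  }
  cfg
}

#' Default configuration calibrated to the reference study population
#'
#' Reproduces the structure of the evaluated medical-area cohort: 450
#' hospitalizations (internal medicine 349, neurology 39, pneumology 62)
#' totalling exactly 2884 patient-days, with ward-conditional gender, age
#' class, length-of-stay class, care-setting and discharge-outcome weights,
#' and setting-conditional instability-band and dependence-level mixes, all
#' taken from the published per-ward and per-setting tabulations (weights
#' are the printed counts, normalized). Only internal-medicine patients can
#' be allocated to low care. The mismatch rate is 0: the per-setting
#' severity mixes already embody the allocation inconsistency observed in
#' the source population.
#'
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
#' @examples
#' cfg <- default_paper_config()
#' sum(cfg$n_patients) # 450
#' cfg$total_patient_days # 2884
default_paper_config <- function(...) {
  pm <- function(counts, rows, cols) {
    m <- matrix(counts, nrow = length(rows), byrow = TRUE,
                dimnames = list(rows, cols))
    sweep(m, 1, rowSums(m), "/")
  }
  defaults <- list(
    n_patients = c(internal_medicine = 349L, neurology = 39L, pneumology = 62L),
    total_patient_days = 2884L,
    gender_probs = pm(c(173, 176,
                        13, 26,
                        30, 32), .wards, c("male", "female")),
    age_class_probs = pm(c(24, 41, 81, 139, 64,
                           9, 6, 13, 10, 1,
                           6, 6, 29, 15, 6),
                         .wards, paste0("age", 1:5)),
    los_class_probs = pm(c(75, 194, 62, 18,
                           0, 24, 6, 9,
                           14, 39, 7, 2),
                         .wards, paste0("los", 1:4)),
    setting_probs = pm(c(11, 10, 280, 48,
                         1, 5, 33, 0,
                         5, 8, 49, 0), .wards, .settings),
    outcome_probs = pm(c(239, 7, 40, 0, 6, 2, 3, 11, 41,
                         28, 2, 0, 0, 4, 2, 0, 0, 3,
                         50, 1, 1, 0, 0, 1, 0, 2, 7), .wards, .outcomes),
    news_band_probs = pm(c(31, 35, 13,
                           123, 55, 7,
                           1888, 269, 140,
                           205, 67, 55), .settings, .news_bands),
    micd_level_probs = pm(c(30, 44, 5,
                            59, 117, 9,
                            1289, 855, 153,
                            58, 182, 83), .settings, .micd_levels),
    mismatch_rate = 0
  )
  do.call(cohort_config, modifyList(defaults, list(...)))
}

#' Repair a sampled length-of-stay vector to an exact day total
#'
#' Perturbs a vector of stay lengths minimally — unit decrements of
#' randomly chosen entries above 1, or unit increments of randomly chosen
#' entries — until it sums to `target`, keeping every stay at least one
#' day. Deterministic given the RNG state.
#'
#' @param sampled_los Integer vector of stay lengths (each >= 1).
#' @param target Required sum; must be at least `length(sampled_los)`.
#' @return Integer vector with `sum(...) == target` and all entries >= 1.
#' @export
#' @examples
#' set.seed(1)
#' sum(repair_total_days(c(3, 3, 3), 10)) # 10
repair_total_days <- function(sampled_los, target) {
  los <- as.integer(sampled_los)
  n <- length(los)
  if (any(los < 1)) stop_config("all stay lengths must be >= 1")
  if (target < n) {
    stop_config(sprintf(
      "infeasible repair: target (%d) below one day per patient (%d)",
      target, n
    ))
  }
  total <- sum(los)
  while (total > target) {
    eligible <- which(los > 1)
    i <- eligible[sample.int(length(eligible), 1)]
    los[i] <- los[i] - 1L
    total <- total - 1L
  }
  while (total < target) {
    i <- sample.int(n, 1)
    los[i] <- los[i] + 1L
    total <- total + 1L
  }
  los
}

#' Generate a seeded synthetic hospital cohort
#'
#' Latent-first simulation: each patient gets a ward, demographics, a stay
#' and one or two setting intervals; each patient-day draws a latent
#' instability band from the setting's configured mix and each interval
#' draws a latent dependence level; bands and levels are then *realized* as
#' concrete vital signs (values sampled inside the band-consistent regions
#' of the band table) and concrete dimension levels (summing into the
#' target dependence range), so re-scoring the realized data recovers the
#' latent classes exactly. If `mismatch_rate > 0`, that fraction of
#' patient-days is re-assigned to a setting inconsistent with the day's
#' complexity class and intervals are rebuilt.
#'
#' Randomness is consumed in four seeded streams in a fixed order —
#' patients, days, vitals, dimensions — so extending one stage cannot shift
#' draws in another. The same `config` and `seed` reproduce the cohort
#' bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return A validated [care_cohort()], with the config and seed attached
#'   as attributes `config` and `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_patients = c(internal_medicine = 4, neurology = 1, pneumology = 1)
#' ), seed = 42)
#' coh
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(seed, {
    stream_seeds <- sample.int(2147483646L, 4)
    patients <- generate_patients(config, stream_seeds[1])
    day_tab <- generate_latent_days(patients, config, stream_seeds[2])
    vitals <- realize_vitals(day_tab$days, config, stream_seeds[3])
    assessments <- realize_assessments(day_tab$intervals, patients, config,
                                       stream_seeds[4])
    coh <- care_cohort(
      patients = patients$table,
      settings = day_tab$intervals |>
        dplyr::select("patient_id", "start_date", "end_date", "setting"),
      vitals = vitals,
      assessments = assessments
    )
    attr(coh, "config") <- config
    attr(coh, "seed") <- seed
    coh
  })
}

# -- generation phases --------------------------------------------------

resample <- function(x, n = 1, prob = NULL) {
  x[sample.int(length(x), n, replace = n > 1, prob = prob)]
}

generate_patients <- function(config, stream_seed) {
  set.seed(stream_seed)
  rows <- list()
  for (w in .wards) {
    n <- config$n_patients[[w]]
    if (n == 0) next
    age_cls <- sample.int(ncol(config$age_class_probs), n, replace = TRUE,
                          prob = config$age_class_probs[w, ])
    los_cls <- sample.int(ncol(config$los_class_probs), n, replace = TRUE,
                          prob = config$los_class_probs[w, ])
    rows[[w]] <- tibble::tibble(
      ward = w,
      gender = resample(c("male", "female"), n, prob = config$gender_probs[w, ]),
      age = vapply(age_cls, function(k) {
        b <- config$age_class_bounds[[k]]
        resample(seq(b[1], b[2]))
      }, numeric(1)),
      los = vapply(los_cls, function(k) {
        b <- config$los_class_bounds[[k]]
        as.integer(resample(seq(b[1], b[2])))
      }, integer(1)),
      setting0 = resample(.settings, n, prob = config$setting_probs[w, ]),
      outcome = resample(.outcomes, n, prob = config$outcome_probs[w, ]),
      admission_offset = resample(seq_len(config$admission_spread_days), n) - 1L,
      drg_value = round(rlnorm(n, config$drg_meanlog, config$drg_sdlog), 2)
    )
  }
  tab <- dplyr::bind_rows(rows)
  tab$patient_id <- sprintf("P%04d", seq_len(nrow(tab)))
  if (!is.null(config$total_patient_days)) {
    tab$los <- repair_total_days(tab$los, config$total_patient_days)
  }
  tab$admission_date <- config$window_start + tab$admission_offset
  tab$discharge_date <- tab$admission_date + tab$los

  # optional single mid-stay transfer to a different admissible setting
  tab$transfer_day <- NA_integer_
  tab$setting1 <- NA_character_
  for (i in seq_len(nrow(tab))) {
    w <- tab$ward[i]
    alt <- .settings[config$setting_probs[w, ] > 0 & .settings != tab$setting0[i]]
    if (tab$los[i] >= 2 && length(alt) > 0 &&
        runif(1) < config$transfer_prob) {
      tab$transfer_day[i] <- resample(seq_len(tab$los[i] - 1))
      p_alt <- config$setting_probs[w, alt]
      tab$setting1[i] <- resample(alt, prob = p_alt / sum(p_alt))
    }
  }
  table <- tibble::tibble(
    patient_id = tab$patient_id,
    ward = tab$ward,
    age = tab$age,
    gender = tab$gender,
    admission_date = tab$admission_date,
    discharge_date = tab$discharge_date,
    outcome = tab$outcome,
    admission_source = "community",
    admission_type = "inpatient",
    drg_value = tab$drg_value
  )
  list(table = table, internal = tab)
}

generate_latent_days <- function(patients, config, stream_seed) {
  set.seed(stream_seed)
  tab <- patients$internal
  days <- purrr::pmap_dfr(
    tab[, c("patient_id", "admission_date", "los", "setting0", "setting1",
            "transfer_day")],
    function(patient_id, admission_date, los, setting0, setting1, transfer_day) {
      offs <- seq_len(los) - 1L
      setting <- rep(setting0, los)
      interval <- rep(1L, los)
      if (!is.na(transfer_day)) {
        setting[offs >= transfer_day] <- setting1
        interval[offs >= transfer_day] <- 2L
      }
      tibble::tibble(patient_id = patient_id,
                     date = admission_date + offs,
                     setting = setting, interval = interval)
    }
  )
  # latent severity: band per day, dependence level per interval
  days$news_band <- vapply(days$setting, function(s) {
    resample(.news_bands, prob = config$news_band_probs[s, ])
  }, character(1))
  ivl_key <- paste(days$patient_id, days$interval)
  ivl_first <- !duplicated(ivl_key)
  ivl_levels <- vapply(days$setting[ivl_first], function(s) {
    resample(.micd_levels, prob = config$micd_level_probs[s, ])
  }, character(1))
  names(ivl_levels) <- ivl_key[ivl_first]
  days$micd_level <- unname(ivl_levels[ivl_key])

  if (config$mismatch_rate > 0) {
    icc <- as.character(classify_icc(days$news_band, days$micd_level,
                                     config$icc_matrix))
    flip <- runif(nrow(days)) < config$mismatch_rate
    mapping <- config$consistency_mapping
    for (i in which(flip)) {
      inconsistent <- .settings[unname(mapping[.settings]) != icc[i]]
      days$setting[i] <- resample(inconsistent)
    }
  }

  # rebuild intervals as runs of constant (setting, dependence level)
  days <- days |> dplyr::arrange(.data$patient_id, .data$date)
  key <- paste(days$setting, days$micd_level)
  new_run <- !duplicated(days$patient_id) |
    c(TRUE, key[-1] != key[-length(key)])
  days$interval <- stats::ave(as.integer(new_run), days$patient_id,
                              FUN = cumsum)
  intervals <- days |>
    dplyr::group_by(.data$patient_id, .data$interval) |>
    dplyr::summarise(
      start_date = min(.data$date),
      end_date = max(.data$date) + 1,
      setting = .data$setting[1],
      micd_level = .data$micd_level[1],
      .groups = "drop"
    )
  list(days = days, intervals = intervals)
}

# Realization regions: band-table intervals clipped to plausible clinical
# ranges so synthetic vitals resemble ward observations (an unbounded
# printed interval like "HR >= 131" is sampled from 131-180).
.plausible <- list(
  respiration_rate = c(4, 40), spo2 = c(75, 100), temperature = c(32, 41.5),
  systolic_bp = c(60, 260), heart_rate = c(30, 180)
)

realization_regions <- function(bands) {
  params <- names(.plausible)
  out <- list()
  for (p in params) {
    step <- if (p == "temperature") 0.1 else 1
    regions <- list()
    for (iv in bands[[p]]) {
      lo <- max(iv$min, .plausible[[p]][1])
      hi <- min(iv$max, .plausible[[p]][2])
      if (lo <= hi) {
        regions[[length(regions) + 1]] <-
          list(score = iv$score, values = seq(lo, hi, by = step))
      }
    }
    out[[p]] <- regions
  }
  out
}

# Randomly decompose a target NEWS total into admissible component scores:
# five physiological sub-scores 0-3, AVPU 0 or 3, oxygen add-on 0 or 2.
compose_news_scores <- function(target) {
  physio <- c(respiration_rate = 0L, spo2 = 0L, temperature = 0L,
              systolic_bp = 0L, heart_rate = 0L)
  avpu <- 0L; o2 <- 0L
  remaining <- target
  while (remaining > 0) {
    opts <- names(physio)[physio < 3L]
    if (avpu == 0L && remaining >= 3L) opts <- c(opts, ".avpu")
    if (o2 == 0L && remaining >= 2L) opts <- c(opts, ".o2")
    pick <- resample(opts)
    if (pick == ".avpu") {
      avpu <- 3L; remaining <- remaining - 3L
    } else if (pick == ".o2") {
      o2 <- 2L; remaining <- remaining - 2L
    } else {
      physio[pick] <- physio[pick] + 1L
      remaining <- remaining - 1L
    }
  }
  list(physio = physio, avpu = avpu, o2 = o2)
}

realize_vitals <- function(days, config, stream_seed) {
  set.seed(stream_seed)
  regions <- realization_regions(config$bands)
  cp <- config$bands$band_cutpoints
  target_pool <- list(
    stable = 0:cp$stable_max,
    unstable = (cp$stable_max + 1):cp$unstable_max,
    critical = seq(config$critical_total_range[1],
                   config$critical_total_range[2])
  )
  n <- nrow(days)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    target <- resample(target_pool[[days$news_band[i]]])
    comp <- compose_news_scores(target)
    vals <- vapply(names(comp$physio), function(p) {
      cand <- Filter(function(r) r$score == comp$physio[[p]], regions[[p]])
      resample(resample(cand)[[1]]$values)
    }, numeric(1))
    out[[i]] <- tibble::tibble(
      patient_id = days$patient_id[i],
      observed_at = days$date[i],
      respiration_rate = vals[["respiration_rate"]],
      spo2 = vals[["spo2"]],
      supplemental_oxygen = comp$o2 > 0L,
      temperature = round(vals[["temperature"]], 1),
      systolic_bp = vals[["systolic_bp"]],
      heart_rate = vals[["heart_rate"]],
      avpu = if (comp$avpu == 0L) "A" else resample(c("V", "P", "U"))
    )
  }
  dplyr::bind_rows(out)
}

# Randomly decompose a target mICD total into eight 1-4 dimension levels.
compose_micd_levels <- function(target) {
  levels <- rep(1L, 8)
  remaining <- target - 8L
  while (remaining > 0) {
    i <- resample(which(levels < 4L))
    levels[i] <- levels[i] + 1L
    remaining <- remaining - 1L
  }
  stats::setNames(levels, .micd_dimensions)
}

realize_assessments <- function(intervals, patients, config, stream_seed) {
  set.seed(stream_seed)
  ranges <- micd_level_ranges(config$scheme)
  adm <- stats::setNames(patients$table$admission_date,
                         patients$table$patient_id)
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    rng <- ranges[[intervals$micd_level[i]]]
    target <- resample(seq(rng[1], rng[2]))
    lv <- compose_micd_levels(target)
    first <- intervals$interval[i] == 1L
    out[[i]] <- tibble::tibble(
      patient_id = intervals$patient_id[i],
      assessed_at = intervals$start_date[i],
      context = if (first) "admission" else "setting_transfer",
      !!!as.list(lv)
    )
  }
  dplyr::bind_rows(out)
}
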