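# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixtures are the reference day-count tabulations in extdata.

make_vitals_row <- function(patient_id, observed_at, rr = 16, spo2 = 98,
                            o2 = FALSE, temp = 37, sbp = 120, hr = 70,
                            avpu = "A") {
  tibble::tibble(
    patient_id = patient_id, observed_at = as.Date(observed_at),
    respiration_rate = rr, spo2 = spo2, supplemental_oxygen = o2,
    temperature = temp, systolic_bp = sbp, heart_rate = hr, avpu = avpu
  )
}

make_assessment_row <- function(patient_id, assessed_at, context,
                                levels = rep(1, 8)) {
  out <- tibble::tibble(patient_id = patient_id,
                        assessed_at = as.Date(assessed_at),
                        context = context)
  dims <- micd_dimension_names()
  for (i in seq_along(dims)) out[[dims[i]]] <- levels[i]
  out
}

make_patient_row <- function(patient_id, ward = "internal_medicine",
                             admission, discharge,
                             outcome = "ordinary_discharge",
                             admission_source = "community",
                             admission_type = "inpatient",
                             age = 80, gender = "female", drg = 3000) {
  tibble::tibble(
    patient_id = patient_id, ward = ward, age = age, gender = gender,
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    outcome = outcome, admission_source = admission_source,
    admission_type = admission_type, drg_value = drg
  )
}

# Three-day stay transferred medium -> low on day 2, with a dependence
# re-assessment at the transfer; two observations on day 1 (totals 3, 6).
make_transfer_cohort <- function() {
  patients <- make_patient_row("T1", admission = "2020-01-20",
                               discharge = "2020-01-23")
  settings <- tibble::tibble(
    patient_id = "T1",
    start_date = as.Date(c("2020-01-20", "2020-01-21")),
    end_date = as.Date(c("2020-01-21", "2020-01-23")),
    setting = c("medium", "low")
  )
  vitals <- dplyr::bind_rows(
    # total 3: HR 95 (1) + O2 (2)
    make_vitals_row("T1", "2020-01-20", hr = 95, o2 = TRUE),
    # total 6: RR 22 (2) + SpO2 93 (2) + SBP 105 (1) + HR 95 (1)
    make_vitals_row("T1", "2020-01-20", rr = 22, spo2 = 93, sbp = 105, hr = 95),
    make_vitals_row("T1", "2020-01-21"),  # total 0
    make_vitals_row("T1", "2020-01-22", rr = 26, spo2 = 90, o2 = TRUE,
                    temp = 39.5, sbp = 85, hr = 135, avpu = "U")  # total 19
  )
  assessments <- dplyr::bind_rows(
    make_assessment_row("T1", "2020-01-20", "admission", rep(2, 8)),      # 16
    make_assessment_row("T1", "2020-01-21", "setting_transfer", rep(3, 8)) # 24
  )
  care_cohort(patients, settings, vitals, assessments)
}

# Single-interval stay builder used by inclusion/summary tests.
simple_cohort <- function(patients) {
  settings <- tibble::tibble(
    patient_id = patients$patient_id,
    start_date = patients$admission_date,
    end_date = patients$discharge_date,
    setting = "medium"
  )
  vitals <- dplyr::bind_rows(lapply(seq_len(nrow(patients)), function(i) {
    dplyr::bind_rows(lapply(
      seq(patients$admission_date[i], patients$discharge_date[i] - 1, "day"),
      function(d) make_vitals_row(patients$patient_id[i], d)
    ))
  }))
  assessments <- dplyr::bind_rows(lapply(seq_len(nrow(patients)), function(i) {
    make_assessment_row(patients$patient_id[i], patients$admission_date[i],
                        "admission", rep(2, 8))
  }))
  care_cohort(patients, settings, vitals, assessments)
}

# Degenerate severity mixes under which every setting holds exactly the
# complexity class it is intended for (allocation-consistent cohort).
consistent_severity_probs <- function() {
  nb <- matrix(0, 4, 3, dimnames = list(setting_labels(), news_band_labels()))
  ml <- matrix(0, 4, 3, dimnames = list(setting_labels(), micd_level_labels()))
  nb["sub_intensive", "critical"] <- 1; ml["sub_intensive", "high"] <- 1
  nb["high", "critical"] <- 1;          ml["high", "high"] <- 1
  nb["medium", "stable"] <- 1;          ml["medium", "average"] <- 1
  nb["low", "stable"] <- 1;             ml["low", "low"] <- 1
  list(news_band_probs = nb, micd_level_probs = ml)
}

# Expand a wide setting-by-class count table into unit rows for crosstab().
counts_to_rows <- function(counts, value_name) {
  long <- tidyr::pivot_longer(counts, -setting, names_to = value_name,
                              values_to = "n")
  out <- long[rep(seq_len(nrow(long)), long$n), c("setting", value_name)]
  out$setting <- factor(out$setting, levels = setting_labels())
  out[[value_name]] <- factor(out[[value_name]],
                              levels = setdiff(names(counts), "setting"))
  out
}

reference_counts <- function(which = c("instability", "dependence")) {
  which <- match.arg(which)
  path <- system.file(
    "extdata",
    paste0("reference_", which, "_days_by_setting.csv"),
    package = "carecomplexity", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

random_vitals <- function(n) {
  tibble::tibble(
    respiration_rate = sample(4:40, n, replace = TRUE),
    spo2 = sample(75:100, n, replace = TRUE),
    supplemental_oxygen = sample(c(TRUE, FALSE), n, replace = TRUE),
    temperature = round(runif(n, 32, 41.5), 1),
    systolic_bp = sample(60:260, n, replace = TRUE),
    heart_rate = sample(30:180, n, replace = TRUE),
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE,
                  prob = c(0.7, 0.1, 0.1, 0.1))
  )
}
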