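#' Assemble and validate a hospital cohort
#'
#' A `care_cohort` bundles the four tables of a longitudinal inpatient
#' cohort:
#'
#' * `patients`: one row per hospitalization — `patient_id`, `ward`, `age`,
#'   `gender`, `admission_date`, `discharge_date`, `outcome`,
#'   `admission_source` (`community` / `external_ward`), `admission_type`
#'   (`inpatient` / `day_hospital` / `outpatient`), `drg_value` (pass-through
#'   economic value of the Diagnosis Related Group).
#' * `settings`: the care-setting intervals — `patient_id`, `start_date`,
#'   `end_date`, `setting`. Half-open `[start, end)`, contiguous,
#'   non-overlapping and jointly covering `[admission, discharge)`.
#' * `vitals`: timestamped vital-sign observations (see [score_news()]) with
#'   `patient_id` and `observed_at`.
#' * `assessments`: care-dependence assessments (see [score_micd()]) with
#'   `patient_id`, `assessed_at` and `context` (`admission` /
#'   `setting_transfer`); each `setting_transfer` assessment must sit on a
#'   setting-interval boundary.
#'
#' A one-day stay is represented as `discharge_date = admission_date + 1`:
#' stays always satisfy `discharge_date > admission_date`, so every
#' hospitalization contributes at least one patient-day.
#'
#' @param patients,settings,vitals,assessments Data frames as described.
#' @param validate Run the full invariant check (default `TRUE`).
#' @return An object of class `care_cohort`.
#' @export
care_cohort <- function(patients, settings, vitals, assessments,
                        validate = TRUE) {
  x <- structure(
    list(
      patients = tibble::as_tibble(patients),
      settings = tibble::as_tibble(settings),
      vitals = tibble::as_tibble(vitals),
      assessments = tibble::as_tibble(assessments)
    ),
    class = "care_cohort"
  )
  if (validate) validate_cohort(x) else x
}

#' @rdname care_cohort
#' @param x A `care_cohort`.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "care_cohort"))
  errors <- character(0)
  collect <- function(msg) errors <<- c(errors, msg)

  p <- x$patients
  need_p <- c("patient_id", "ward", "age", "gender", "admission_date",
              "discharge_date", "outcome", "admission_source",
              "admission_type", "drg_value")
  miss <- setdiff(need_p, names(p))
  if (length(miss) > 0) {
    stop_validation(paste0("patients table missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  p$admission_date <- as_iso_date(p$admission_date, "patients$admission_date")
  p$discharge_date <- as_iso_date(p$discharge_date, "patients$discharge_date")
  p$ward <- as_label_factor(p$ward, .wards, "ward")
  p$outcome <- as_label_factor(p$outcome, .outcomes, "outcome")
  if (anyDuplicated(p$patient_id)) {
    collect("duplicated patient_id in patients table")
  }
  bad <- which(p$discharge_date <= p$admission_date)
  if (length(bad) > 0) {
    collect(sprintf("discharge_date must be after admission_date (patients %s)",
                    paste(utils::head(p$patient_id[bad], 5), collapse = ", ")))
  }

  s <- x$settings
  need_s <- c("patient_id", "start_date", "end_date", "setting")
  miss <- setdiff(need_s, names(s))
  if (length(miss) > 0) {
    stop_validation(paste0("settings table missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  s$start_date <- as_iso_date(s$start_date, "settings$start_date")
  s$end_date <- as_iso_date(s$end_date, "settings$end_date")
  s$setting <- as_label_factor(s$setting, .settings, "care setting")

  v <- x$vitals
  if (nrow(v) > 0) {
    if (!"observed_at" %in% names(v)) {
      stop_validation("vitals table missing column observed_at")
    }
    v$observed_at <- as_iso_date(v$observed_at, "vitals$observed_at")
  }
  a <- x$assessments
  if (nrow(a) > 0) {
    miss <- setdiff(c("patient_id", "assessed_at", "context"), names(a))
    if (length(miss) > 0) {
      stop_validation(paste0("assessments table missing column(s): ",
                             paste(miss, collapse = ", ")))
    }
    a$assessed_at <- as_iso_date(a$assessed_at, "assessments$assessed_at")
    bad_ctx <- setdiff(unique(a$context), c("admission", "setting_transfer"))
    if (length(bad_ctx) > 0) {
      collect(paste0("invalid assessment context: ",
                     paste(bad_ctx, collapse = ", ")))
    }
  }

  # per-patient interval structure: contiguous, non-overlapping, covering
  split_s <- split(s, s$patient_id)
  for (pid in p$patient_id) {
    si <- split_s[[as.character(pid)]]
    prow <- p[p$patient_id == pid, ]
    if (is.null(si) || nrow(si) == 0) {
      collect(sprintf("patient %s has no setting intervals", pid))
      next
    }
    si <- si[order(si$start_date), ]
    if (si$start_date[1] != prow$admission_date) {
      collect(sprintf("patient %s: first interval does not start at admission", pid))
    }
    if (si$end_date[nrow(si)] != prow$discharge_date) {
      collect(sprintf("patient %s: last interval does not end at discharge", pid))
    }
    if (any(si$end_date <= si$start_date)) {
      collect(sprintf("patient %s: empty setting interval", pid))
    }
    if (nrow(si) > 1 &&
        any(si$start_date[-1] != si$end_date[-nrow(si)])) {
      collect(sprintf("patient %s: setting intervals have a gap or overlap", pid))
    }
    ai <- a[a$patient_id == pid & a$context == "setting_transfer", , drop = FALSE]
    if (nrow(ai) > 0) {
      boundaries <- si$start_date[-1]
      off <- !ai$assessed_at %in% boundaries
      if (any(off)) {
        collect(sprintf(
          "patient %s: setting_transfer assessment not on an interval boundary (%s)",
          pid, paste(as.character(ai$assessed_at[off]), collapse = ", ")
        ))
      }
    }
  }
  orphan <- setdiff(unique(s$patient_id), p$patient_id)
  if (length(orphan) > 0) {
    collect(paste0("settings rows for unknown patient(s): ",
                   paste(utils::head(orphan, 5), collapse = ", ")))
  }

  if (length(errors) > 0) {
    stop_validation(paste0(
      "cohort failed validation with ", length(errors), " problem(s):\n- ",
      paste(errors, collapse = "\n- ")
    ))
  }
  x$patients <- p
  x$settings <- s
  x$vitals <- v
  x$assessments <- a
  x
}

#' @export
print.care_cohort <- function(x, ...) {
  days <- sum(as.integer(x$patients$discharge_date - x$patients$admission_date))
  cat(sprintf(
    "<care_cohort> %d patients, %d patient-days, %d vitals, %d assessments\n",
    nrow(x$patients), days, nrow(x$vitals), nrow(x$assessments)
  ))
  tab <- table(x$patients$ward)
  cat("  wards: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
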