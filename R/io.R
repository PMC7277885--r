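#' Read and write cohort CSV directories
#'
#' The interchange format is a directory of four UTF-8, comma-separated
#' files with ISO-8601 dates: `patients.csv`, `settings.csv`, `vitals.csv`
#' (supplemental oxygen as 0/1, AVPU as A/V/P/U) and `assessments.csv`.
#' `read_cohort()` validates everything on load and reports row-level
#' problems together; `write_cohort()` writes a cohort back out, and the
#' two are inverse on all record fields.
#'
#' @param dir Directory containing (or to receive) the four CSV files.
#' @return `read_cohort()`: a validated [care_cohort()]. `write_cohort()`:
#'   the paths written, invisibly.
#' @export
read_cohort <- function(dir) {
  files <- c(patients = "patients.csv", settings = "settings.csv",
             vitals = "vitals.csv", assessments = "assessments.csv")
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_io(paste0("cohort directory ", dir, " is missing file(s): ",
                   paste(missing, collapse = ", ")))
  }
  read1 <- function(path) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  tabs <- lapply(stats::setNames(paths, names(files)), read1)

  v <- tabs$vitals
  if (nrow(v) > 0) {
    if ("supplemental_oxygen" %in% names(v)) {
      if (!all(v$supplemental_oxygen %in% c(0, 1, TRUE, FALSE))) {
        stop_validation("vitals$supplemental_oxygen must be 0/1")
      }
      v$supplemental_oxygen <- v$supplemental_oxygen == 1
    }
    tabs$vitals <- v
  }
  coh <- care_cohort(tabs$patients, tabs$settings, tabs$vitals,
                     tabs$assessments)
  # surface scoring-level problems (bad AVPU labels, out-of-range
  # dimension levels) at load time rather than first analysis
  if (nrow(coh$vitals) > 0) invisible(score_news(coh$vitals))
  if (nrow(coh$assessments) > 0) invisible(score_micd(coh$assessments))
  coh
}

#' @rdname read_cohort
#' @param cohort A [care_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "care_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop_io(paste0("cannot create directory ", dir))
  v <- cohort$vitals
  if (nrow(v) > 0 && is.logical(v$supplemental_oxygen)) {
    v$supplemental_oxygen <- as.integer(v$supplemental_oxygen)
  }
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    settings = file.path(dir, "settings.csv"),
    vitals = file.path(dir, "vitals.csv"),
    assessments = file.path(dir, "assessments.csv")
  )
  readr::write_csv(cohort$patients, paths["patients"], progress = FALSE)
  readr::write_csv(cohort$settings, paths["settings"], progress = FALSE)
  readr::write_csv(v, paths["vitals"], progress = FALSE)
  readr::write_csv(cohort$assessments, paths["assessments"], progress = FALSE)
  invisible(paths)
}

#' Write tidy analysis reports
#'
#' Writes one CSV per cross-tabulation (counts and one-decimal row
#' percentages side by side, with a `Total` margin row and the chi-square
#' result in trailing columns), the allocation-consistency report, the
#' per-patient summary if given, and a JSON run manifest. Output is
#' byte-stable for identical inputs: fixed column order, fixed number
#' formatting, no timestamps unless requested.
#'
#' @param out_dir Output directory (created if needed).
#' @param crosstabs Named list of [crosstab()] results; each is written to
#'   `<name>.csv`.
#' @param consistency Optional result of [consistency_analysis()].
#' @param summaries Optional result of [per_patient_summary()].
#' @param manifest Optional manifest list from [run_manifest()].
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(out_dir, crosstabs = list(), consistency = NULL,
                          summaries = NULL, manifest = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io(paste0("cannot create directory ", out_dir))
  written <- character(0)
  for (nm in names(crosstabs)) {
    ct <- crosstabs[[nm]]
    stopifnot(inherits(ct, "care_crosstab"))
    counts <- rbind(ct$counts, Total = colSums(ct$counts))
    df <- data.frame(row = rownames(counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (j in seq_len(ncol(counts))) {
      df[[paste0(colnames(counts)[j], "_n")]] <- as.integer(counts[, j])
      df[[paste0(colnames(counts)[j], "_pct")]] <-
        sprintf("%.1f", ct$row_percent[, j])
    }
    df$chi2_stat <- c(sprintf("%.4f", ct$chi2_stat),
                      rep("", nrow(df) - 1))
    df$chi2_dof <- c(ifelse(is.na(ct$chi2_dof), "",
                            as.character(as.integer(ct$chi2_dof))),
                     rep("", nrow(df) - 1))
    df$chi2_p <- c(ifelse(is.na(ct$chi2_p), "", sprintf("%.6g", ct$chi2_p)),
                   rep("", nrow(df) - 1))
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    written <- c(written, path)
  }
  if (!is.null(consistency)) {
    path <- file.path(out_dir, "consistency.csv")
    out <- consistency
    out$proportion <- sprintf("%.4f", out$proportion)
    readr::write_csv(out, path, progress = FALSE)
    written <- c(written, path)
  }
  if (!is.null(summaries)) {
    path <- file.path(out_dir, "per_patient_summary.csv")
    readr::write_csv(summaries, path, progress = FALSE)
    written <- c(written, path)
  }
  if (!is.null(manifest)) {
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, path)
  }
  invisible(written)
}

#' Build a run manifest
#'
#' Records what produced a set of outputs: package version, seed, a stable
#' hash of the configuration, and per-input row counts. Timestamps are
#' opt-in so that reruns stay byte-identical.
#'
#' @param seed Seed used for the run (or `NULL`).
#' @param config Configuration object to hash (or `NULL`).
#' @param inputs Named list of data frames (or file paths) that fed the
#'   run.
#' @param timestamp Include the wall-clock time (default `FALSE`).
#' @return A list suitable for [write_reports()]'s `manifest` argument.
#' @export
run_manifest <- function(seed = NULL, config = NULL, inputs = list(),
                         timestamp = FALSE) {
  input_info <- lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      list(path = x, rows = length(readr::read_lines(x, progress = FALSE)) - 1L)
    } else if (is.data.frame(x)) {
      list(rows = nrow(x))
    } else {
      list()
    }
  })
  m <- list(
    tool = "carecomplexity",
    version = as.character(packageVersion("carecomplexity")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else config_hash(config),
    inputs = input_info
  )
  if (timestamp) m$timestamp <- format(Sys.time(), tz = "UTC")
  m
}

# Platform-stable hash of an R object: md5 of its canonical deparse.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames",
                                      "showAttributes")),
               collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
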