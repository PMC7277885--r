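#' Index of Caring Complexity (ICC)
#'
#' The ICC summarizes a patient's overall care complexity by crossing the
#' clinical-instability band (from the NEWS) with the care-dependence level
#' (from the mICD) through a 3x3 matrix. Higher cells represent higher
#' caring complexity; the default mapping returns `Low` only when both
#' inputs are at their minimum:
#'
#' | band \\ level | low    | average | high |
#' |--------------|--------|---------|------|
#' | stable       | Low    | Medium  | High |
#' | unstable     | Medium | Medium  | High |
#' | critical     | High   | High    | High |
#'
#' The matrix is data, not code: hospitals localize it via
#' [read_icc_matrix()]. Any replacement must be total (all 9 cells) and
#' monotone non-decreasing along both axes, which is validated on load.
#'
#' @param band Instability band(s): `"stable"`, `"unstable"`, `"critical"`.
#' @param level Dependence level(s): `"low"`, `"average"`, `"high"`.
#'   Recycled against `band` if either has length 1.
#' @param matrix An ICC matrix from [icc_default_matrix()] or
#'   [read_icc_matrix()].
#' @return Ordered factor with levels Low < Medium < High.
#' @export
#' @examples
#' classify_icc("stable", "low")     # Low
#' classify_icc("unstable", "low")   # Medium
#' classify_icc("critical", "low")   # High
classify_icc <- function(band, level, matrix = icc_default_matrix()) {
  band <- as_label_factor(band, .news_bands, "instability band")
  level <- as_label_factor(level, .micd_levels, "dependence level")
  if (length(band) == 1) band <- rep(band, length(level))
  if (length(level) == 1) level <- rep(level, length(band))
  if (length(band) != length(level)) {
    stop_validation("band and level must have equal lengths (or length 1)")
  }
  out <- matrix[cbind(as.character(band), as.character(level))]
  factor(out, levels = .icc_levels, ordered = TRUE)
}

#' @rdname classify_icc
#' @export
icc_default_matrix <- function() {
  path <- system.file("extdata", "icc_matrix_default.yaml",
                      package = "carecomplexity", mustWork = TRUE)
  read_icc_matrix(path)
}

#' @rdname classify_icc
#' @param path Path to a YAML file keyed by band then level.
#' @export
read_icc_matrix <- function(path) {
  if (!file.exists(path)) stop_io(paste0("ICC matrix file not found: ", path))
  raw <- yaml::read_yaml(path)
  m <- matrix(NA_character_, nrow = 3, ncol = 3,
              dimnames = list(.news_bands, .micd_levels))
  for (b in .news_bands) {
    for (l in .micd_levels) {
      cell <- raw[[b]][[l]]
      if (is.null(cell)) {
        stop_config(sprintf("ICC matrix missing cell (%s, %s)", b, l))
      }
      m[b, l] <- as.character(cell)
    }
  }
  validate_icc_matrix(m)
}

validate_icc_matrix <- function(m) {
  bad <- setdiff(unique(as.vector(m)), .icc_levels)
  if (length(bad) > 0) {
    stop_config(paste0("ICC matrix cells must be Low/Medium/High; found: ",
                       paste(bad, collapse = ", ")))
  }
  rank <- function(x) match(x, .icc_levels)
  for (i in seq_len(nrow(m))) {
    if (is.unsorted(rank(m[i, ]))) {
      stop_config("ICC matrix must be monotone non-decreasing along dependence levels")
    }
  }
  for (j in seq_len(ncol(m))) {
    if (is.unsorted(rank(m[, j]))) {
      stop_config("ICC matrix must be monotone non-decreasing along instability bands")
    }
  }
  m
}
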