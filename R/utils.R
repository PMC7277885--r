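#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical tables round
#' half up. Used everywhere a percentage is printed to one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(16.85, 1) # 16.9, where round() gives 16.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Structured conditions: every user-facing failure carries a class so
# callers (and the CLI) can map it to an exit code.
stop_validation <- function(msg, ...) {
  abort(msg, class = c("carecomplexity_validation_error", "carecomplexity_error"), ...)
}

stop_range <- function(msg, ...) {
  abort(msg, class = c("carecomplexity_range_error", "carecomplexity_error"), ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = c("carecomplexity_config_error", "carecomplexity_error"), ...)
}

stop_io <- function(msg, ...) {
  abort(msg, class = c("carecomplexity_io_error", "carecomplexity_error"), ...)
}

# Assert that `x` contains only the allowed labels; returns a factor with
# the full level set (zero-count levels are retained in tabulations).
as_label_factor <- function(x, levels, what, ordered = FALSE) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "invalid %s label(s): %s (expected one of %s)",
      what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")
    ))
  }
  factor(x, levels = levels, ordered = ordered)
}

# Parse ISO-8601 dates strictly, with an informative error.
as_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "malformed date(s) in %s (expected ISO-8601 YYYY-MM-DD): %s",
      what, paste(utils::head(as.character(x)[bad], 5), collapse = ", ")
    ))
  }
  out
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
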