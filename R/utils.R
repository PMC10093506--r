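#' @import data.table
#' @importFrom stats median quantile rbinom rexp rlnorm rnorm runif sd setNames qnorm
#' @importFrom utils packageVersion head
#' @importFrom tools md5sum
NULL

#' Null-coalescing operator
#' @param x,y values; `y` is returned when `x` is `NULL`.
#' @return `x` unless it is `NULL`, else `y`.
#' @name op-null-default
#' @keywords internal
#' @export
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabulated percentages in
#' pharmacovigilance reports conventionally round half up. Used by
#' [percent_int()].
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to the nearest
#' integer, the convention used for all percentage columns in the summary
#' tables.
#'
#' @param numerator,denominator nonnegative counts (vectorised).
#' @return integer vector of percentages.
#' @examples
#' percent_int(287, 1409)  # 20
#' percent_int(726, 1409)  # 52
#' @export
percent_int <- function(numerator, denominator) {
  if (!is.numeric(numerator) || !is.numeric(denominator)) {
    stop("percent_int(): numerator and denominator must be numeric")
  }
  if (any(denominator <= 0)) {
    stop("percent_int(): denominator must be strictly positive")
  }
  as.integer(round_half_up(100 * numerator / denominator))
}

# enum vocabularies of the tabular dialect (see inst/extdata/dialect.md)
ROLE_LEVELS        <- c("suspected", "interacting", "concomitant")
ACTION_LEVELS      <- c("withdrawn", "dose_reduced", "continued", "unknown")
OUTCOME_LEVELS     <- c("recovered", "recovering", "not_recovered",
                        "recovered_with_sequelae", "fatal", "unknown")
REPORTER_LEVELS    <- c("physician", "pharmacist", "other_health_professional",
                        "consumer", "unknown")
SEX_LEVELS         <- c("male", "female", "unknown")
SERIOUSNESS_LEVELS <- c("serious", "not_serious", "unknown")
SERIOUS_FLAG_LEVELS <- c("hospitalization", "life_threatening", "death",
                         "disability", "congenital_anomaly",
                         "other_medically_significant")

.check_enum <- function(x, allowed, column, table_name) {
  bad <- which(!is.na(x) & !(x %in% allowed))
  if (length(bad)) {
    stop(sprintf("%s: invalid %s value '%s' at row %d (allowed: %s)",
                 table_name, column, x[bad[1L]], bad[1L],
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.as_date <- function(x, column, table_name) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s '%s' at row %d (expected YYYY-MM-DD)",
                 table_name, column, x[bad[1L]], bad[1L]), call. = FALSE)
  }
  out
}

# split a pipe-joined flag cell into a character vector
.split_flags <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}
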