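#' Round half away from zero
#'
#' Table-style rounding: 0.05 rounds to 0.1, matching how epidemiological
#' reports print percentages, rather than banker's rounding used by
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 50.25), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## days per year used for all age arithmetic (18+ eligibility, +/-1 y matching)
DAYS_PER_YEAR <- 365.25

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

## age in (fractional) years at a date
age_years <- function(date, birthdate) {
  as.numeric(date - birthdate) / DAYS_PER_YEAR
}

check_columns <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
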