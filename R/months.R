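# Calendar-month keys.
#
# Months are represented throughout the package as "YYYY-MM" character
# strings: they sort correctly as plain strings, behave in joins and as
# names, and the helpers below supply the arithmetic (sequence, difference,
# month-end cutoff) the snapshot-selection rules need. All timestamps are
# interpreted in UTC.

#' Build a month key
#'
#' @param year Integer year.
#' @param month Integer month, 1-12.
#' @return A `"YYYY-MM"` character vector.
#' @export
#' @examples
#' month_key(2018, 4)
month_key <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  sprintf("%04d-%02d", as.integer(year), as.integer(month))
}

#' Coerce to a month key
#'
#' Accepts `"YYYY-MM"` strings (possibly with a day suffix), `Date` or
#' `POSIXct` values.
#'
#' @param x Vector to coerce.
#' @return A `"YYYY-MM"` character vector.
#' @export
as_month_key <- function(x) {
  if (inherits(x, c("Date", "POSIXct", "POSIXlt"))) {
    return(format(x, "%Y-%m", tz = "UTC"))
  }
  x <- as.character(x)
  out <- sub("^(\\d{4})-(\\d{2}).*$", "\\1-\\2", x)
  bad <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", out)
  if (any(bad)) {
    stop("not a valid month key: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

# months since year 0, for arithmetic
month_index <- function(mk) {
  mk <- as_month_key(mk)
  as.integer(substr(mk, 1, 4)) * 12L + as.integer(substr(mk, 6, 7)) - 1L
}

index_to_month <- function(i) {
  month_key(i %/% 12L, i %% 12L + 1L)
}

#' Sequence of consecutive months
#'
#' @param from,to Month keys (inclusive).
#' @return Character vector of month keys.
#' @export
month_seq <- function(from, to) {
  a <- month_index(from)
  b <- month_index(to)
  if (b < a) stop("'to' precedes 'from'", call. = FALSE)
  index_to_month(seq(a, b))
}

#' Number of months from one key to another
#'
#' @param from,to Month keys.
#' @return Integer; positive when `to` is later.
#' @export
month_diff <- function(from, to) {
  month_index(to) - month_index(from)
}

#' Shift a month key
#'
#' @param mk Month key.
#' @param by Integer number of months (may be negative).
#' @export
month_shift <- function(mk, by = 1L) {
  index_to_month(month_index(mk) + as.integer(by))
}

#' Month-end cutoff instant
#'
#' The last second of the month (23:59:59 on its last day), in UTC: the
#' instant used to pick the panel version that represents a month.
#'
#' @param mk Month key.
#' @return `POSIXct` (UTC).
#' @export
month_end <- function(mk) {
  mk <- as_month_key(mk)
  first_next <- as.Date(paste0(month_shift(mk, 1L), "-01"))
  as.POSIXct(paste(first_next - 1L, "23:59:59"), tz = "UTC")
}

#' Last calendar day of a month
#'
#' @param mk Month key.
#' @return `Date`.
#' @export
month_end_date <- function(mk) {
  as.Date(paste0(month_shift(as_month_key(mk), 1L), "-01")) - 1L
}
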