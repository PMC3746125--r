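#' Semiannual period labels
#'
#' Market observations are semiannual: one price/share reading around May/June
#' ("H1") and one around November/December ("H2") of each year. Periods are
#' encoded as `"YYYY-H1"` / `"YYYY-H2"`, which sort chronologically as plain
#' strings. Each period carries one fixed representative calendar date so that
#' tax-regime and deflator lookups are deterministic: 1 June for H1 and
#' 1 November for H2 (optionally 1 October for 2005-H2, where price
#' publication stopped a month early).
#'
#' @param year Integer vector of calendar years.
#' @param half `"H1"` or `"H2"` (recycled against `year`).
#' @return `period_label()` returns a character vector of period labels.
#' @examples
#' period_label(2006, "H2")
#' period_date("2006-H2")
#' period_seq(2005, 2007)
#' @export
period_label <- function(year, half) {
  stopifnot(all(half %in% c("H1", "H2")))
  paste0(year, "-", half)
}

#' @rdname period_label
#' @param period Character vector of period labels.
#' @return `period_year()` and `period_half()` return the components.
#' @export
period_year <- function(period) {
  check_period(period)
  as.integer(substr(period, 1L, 4L))
}

#' @rdname period_label
#' @export
period_half <- function(period) {
  check_period(period)
  substr(period, 6L, 7L)
}

#' @rdname period_label
#' @param oct_2005 If `TRUE`, date 2005-H2 at 1 October instead of
#'   1 November.
#' @return `period_date()` returns a `Date` vector of representative dates.
#' @export
period_date <- function(period, oct_2005 = FALSE) {
  yr <- period_year(period)
  half <- period_half(period)
  month <- ifelse(half == "H1", "06", "11")
  if (oct_2005) {
    month[period == "2005-H2"] <- "10"
  }
  as.Date(paste0(yr, "-", month, "-01"))
}

#' @rdname period_label
#' @param from,to First and last calendar year of the sequence.
#' @return `period_seq()` returns all period labels from `from`-H1 to
#'   `to`-H2 in chronological order.
#' @export
period_seq <- function(from, to) {
  stopifnot(from <= to)
  as.vector(t(outer(seq(from, to), c("H1", "H2"), period_label)))
}

check_period <- function(period) {
  ok <- grepl("^[0-9]{4}-H[12]$", period)
  if (!all(ok)) {
    abort(paste0(
      "Invalid period label(s): ",
      paste(unique(period[!ok]), collapse = ", "),
      ". Expected \"YYYY-H1\" or \"YYYY-H2\"."
    ))
  }
  invisible(period)
}

#' Round half away from zero for reporting
#'
#' Published pence-per-pack figures are given to one decimal; internal
#' computation keeps full precision and only report-time output is rounded,
#' half away from zero (so 0.05 -> 0.1 and -0.05 -> -0.1), unlike base
#' `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1, the reporting precision).
#' @return Rounded numeric vector.
#' @examples
#' round_report(c(4.15, -4.15, 4.1667))
#' @export
round_report <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
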