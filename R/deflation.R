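#' Monthly price-index series
#'
#' A consumer (or retail) price index as a monthly series, used to express
#' nominal pence in real, base-period money. The tibble has columns `month`
#' (a `Date`, first of month) and `value` (positive index level), plus a
#' `base_month` attribute naming the period whose money all deflated amounts
#' are expressed in.
#'
#' @param month Dates (coerced with `as.Date()`; snapped to the first of the
#'   month).
#' @param value Positive index levels.
#' @param base_month The base month (must be present in the series). Defaults
#'   to the last month.
#' @return A tibble with class `index_series`.
#' @examples
#' cpi <- index_series(c("2009-11-01", "2010-06-01"), c(98, 100),
#'                     base_month = "2010-06-01")
#' deflate(100, as.Date("2009-11-15"), cpi)
#' @export
index_series <- function(month, value, base_month = NULL) {
  month <- snap_month(as.Date(month))
  if (anyDuplicated(month)) abort("Duplicate months in index series.")
  if (any(!is.finite(value) | value <= 0)) {
    abort("Index values must be positive and finite.")
  }
  ord <- order(month)
  series <- tibble(month = month[ord], value = as.numeric(value)[ord])
  base_month <- if (is.null(base_month)) max(series$month) else
    snap_month(as.Date(base_month))
  if (!base_month %in% series$month) {
    abort(paste0("base_month ", format(base_month), " is not in the series."))
  }
  attr(series, "base_month") <- base_month
  class(series) <- unique(c("index_series", class(series)))
  series
}

snap_month <- function(date) {
  as.Date(format(date, "%Y-%m-01"))
}

#' @rdname index_series
#' @param series An [index_series()] tibble.
#' @return `index_base()` returns the base month.
#' @export
index_base <- function(series) {
  attr(series, "base_month")
}

#' Read an index series from CSV
#'
#' Expected columns: `period` (ISO month, `YYYY-MM` or a full date) and
#' `index_value`.
#'
#' @param path Path to a CSV file.
#' @param base_month Base month passed to [index_series()].
#' @return An [index_series()] tibble.
#' @export
read_index_series <- function(path, base_month = NULL) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(c("period", "index_value"), names(raw))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  month <- as.character(raw$period)
  month <- ifelse(grepl("^[0-9]{4}-[0-9]{2}$", month),
                  paste0(month, "-01"), month)
  index_series(month, raw$index_value, base_month = base_month)
}

#' @rdname read_index_series
#' @param series An [index_series()] tibble.
#' @param header Optional comment lines written before the CSV.
#' @export
write_index_series <- function(series, path, header = NULL) {
  out <- tibble(period = format(series$month, "%Y-%m"),
                index_value = series$value)
  write_csv_with_header(out, path, header)
}

#' Index level at a date
#'
#' The index is matched using the latest monthly value at or before the date.
#' A date before the first month is an error — no silent extrapolation.
#'
#' @param series An [index_series()] tibble.
#' @param date Date vector.
#' @return Numeric index levels.
#' @export
index_value_at <- function(series, date) {
  date <- as.Date(date)
  idx <- findInterval(snap_month(date), series$month)
  if (any(idx == 0)) {
    abort(paste0(
      "Index series starts at ", format(min(series$month)),
      "; no value available for ",
      paste(format(date[idx == 0]), collapse = ", "), "."
    ))
  }
  series$value[idx]
}

#' Deflate nominal pence to base-period money
#'
#' `nominal * index(base) / index(date)`. Linear in `nominal`, so deflating a
#' difference equals the difference of deflated values — net-of-tax revenue
#' may be deflated before or after subtracting tax.
#'
#' @param nominal Nominal amounts (pence). Vectorised with `date`.
#' @param date Observation dates.
#' @param series An [index_series()] tibble.
#' @return Real amounts in base-month pence.
#' @export
deflate <- function(nominal, date, series) {
  base_value <- index_value_at(series, index_base(series))
  nominal * base_value / index_value_at(series, date)
}

#' @rdname deflate
#' @description `inflate()` is the inverse: base-period pence back to nominal
#'   pence of `date`.
#' @param real Real amounts in base-month pence.
#' @export
inflate <- function(real, date, series) {
  base_value <- index_value_at(series, index_base(series))
  real * index_value_at(series, date) / base_value
}

#' Rebase an index series
#'
#' Rescales so the new base month maps to 100; all period-to-period growth
#' ratios are preserved exactly.
#'
#' @param series An [index_series()] tibble.
#' @param new_base A month present in the series.
#' @return An [index_series()] tibble with base value 100.
#' @export
rebase <- function(series, new_base) {
  new_base <- snap_month(as.Date(new_base))
  if (!new_base %in% series$month) {
    abort(paste0("new_base ", format(new_base), " is not in the series."))
  }
  scale <- 100 / series$value[series$month == new_base]
  index_series(series$month, series$value * scale, base_month = new_base)
}
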