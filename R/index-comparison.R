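#' Most popular price category (MPPC) price
#'
#' The retail price point accounting for the largest volume share —
#' historically the EU reference price for setting cigarette excise. Prices
#' are grouped into bins of width `price_resolution` (default 1 penny, since
#' "price category" has no official bin definition); the winning bin is the
#' one with the largest summed volume share, represented by its
#' volume-weighted mean price. Ties are broken towards the lower price.
#'
#' @param panel A panel tibble.
#' @param periods Periods to evaluate (default: all present).
#' @param price_resolution Bin width in pence (default 1).
#' @return A tibble `period, mppc` (pence per pack).
#' @export
mppc_price <- function(panel, periods = NULL, price_resolution = 1) {
  stopifnot(price_resolution > 0)
  periods <- periods %||% sort(unique(panel$period))
  rows <- panel |>
    dplyr::filter(.data$period %in% periods, .data$volume_share > 0)
  missing <- setdiff(periods, unique(rows$period))
  if (length(missing) > 0) {
    abort(paste0("No positive-share observations in period(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows |>
    dplyr::mutate(bin = round(.data$nominal_price / price_resolution)) |>
    dplyr::group_by(.data$period, .data$bin) |>
    dplyr::summarise(
      share = sum(.data$volume_share),
      price = sum(.data$volume_share * .data$nominal_price) /
        sum(.data$volume_share),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$period) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$price, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(period = .data$period, mppc = .data$price)
}

#' Whole-market weighted average price
#'
#' The volume-share-weighted mean retail price across every listed brand —
#' the reference price the EU moved to in 2011. Zero-share brands contribute
#' nothing.
#'
#' @inheritParams mppc_price
#' @return A tibble `period, wap` (pence per pack).
#' @export
market_wap <- function(panel, periods = NULL) {
  periods <- periods %||% sort(unique(panel$period))
  panel |>
    dplyr::filter(.data$period %in% periods, .data$volume_share > 0) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      wap = sum(.data$volume_share * .data$nominal_price) /
        sum(.data$volume_share),
      .groups = "drop"
    )
}

#' Compare MPPC, weighted-average and external price indices
#'
#' Builds nominal MPPC and whole-market WAP series from a panel, rebases each
#' to 100 at `base_period`, optionally aligns an external index series
#' (e.g. an official retail-price index for cigarettes) rebased the same way,
#' and reports each index's growth over the common span. Because the MPPC
#' tracks the modal (typically premium) price point while the WAP averages
#' over the growing cheap segments, MPPC growth overstates market-wide price
#' growth whenever the modal price point rises faster than the average.
#'
#' @param panel A panel tibble.
#' @param external Optional [index_series()] (monthly); sampled at each
#'   period's representative date.
#' @param base_period Period label at which all indices equal 100 (default:
#'   first common period).
#' @param price_resolution Passed to [mppc_price()].
#' @param oct_2005 Passed to [period_date()].
#' @return An object of class `index_comparison`: a list with `index`
#'   (tibble `period, series, level, index`), `growth` (tibble
#'   `series, growth_pct` over the full span) and `base_period`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
compare_indices <- function(panel, external = NULL, base_period = NULL,
                            price_resolution = 1, oct_2005 = FALSE) {
  mppc <- mppc_price(panel, price_resolution = price_resolution) |>
    dplyr::transmute(.data$period, series = "mppc", level = .data$mppc)
  wap <- market_wap(panel) |>
    dplyr::transmute(.data$period, series = "wap", level = .data$wap)
  long <- dplyr::bind_rows(mppc, wap)
  if (!is.null(external)) {
    periods <- sort(unique(long$period))
    dates <- period_date(periods, oct_2005 = oct_2005)
    covered <- dates >= min(external$month)
    if (!all(covered)) {
      warn(paste0(
        "External index does not cover period(s) ",
        paste(periods[!covered], collapse = ", "),
        "; comparison trimmed to the common span."
      ))
      keep <- periods[covered]
      long <- dplyr::filter(long, .data$period %in% keep)
      periods <- keep
      dates <- dates[covered]
    }
    long <- dplyr::bind_rows(long, tibble(
      period = periods, series = "external",
      level = index_value_at(external, dates)
    ))
  }
  common <- long |>
    dplyr::count(.data$period) |>
    dplyr::filter(.data$n == dplyr::n_distinct(long$series)) |>
    dplyr::pull(.data$period)
  long <- dplyr::filter(long, .data$period %in% common)
  base_period <- base_period %||% min(common)
  if (!base_period %in% common) {
    abort(paste0("base_period ", base_period,
                 " is not covered by every series."))
  }
  long <- long |>
    dplyr::group_by(.data$series) |>
    dplyr::mutate(index = 100 * .data$level /
                    .data$level[.data$period == base_period]) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$series, .data$period)
  growth <- long |>
    dplyr::group_by(.data$series) |>
    dplyr::summarise(
      growth_pct = 100 * .data$level[.data$period == max(.data$period)] /
        .data$level[.data$period == base_period] - 100,
      .groups = "drop"
    )
  structure(
    list(index = long, growth = growth, base_period = base_period),
    class = "index_comparison"
  )
}

#' @export
print.index_comparison <- function(x, ...) {
  cat("Price index comparison (base ", x$base_period, " = 100)\n", sep = "")
  print(x$growth)
  invisible(x)
}

#' @rdname compare_indices
#' @param x An `index_comparison` object.
#' @param ... Unused.
#' @export
tidy.index_comparison <- function(x, ...) {
  x$index
}

#' @rdname compare_indices
#' @export
glance.index_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$growth, names_from = "series", values_from = "growth_pct",
    names_glue = "growth_{series}"
  )
  dplyr::mutate(wide, base_period = x$base_period,
                n_periods = dplyr::n_distinct(x$index$period))
}

#' @rdname compare_indices
#' @param object An `index_comparison` object.
#' @export
autoplot.index_comparison <- function(object, ...) {
  ggplot2::ggplot(object$index, ggplot2::aes(
    x = .data$period, y = .data$index, colour = .data$series,
    group = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = NULL, y = paste0("index (", object$base_period, " = 100)"),
      colour = NULL
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
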