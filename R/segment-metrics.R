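#' Weighted average price by segment and period
#'
#' The share-weighted mean retail price within each (segment, period) cell,
#' with shares renormalised within the segment:
#' `sum(share_b * price_b) / sum(share_b)` over the segment's brands. A
#' segment with no positive-share observation in a period yields no row — a
#' missing value, never a zero (the ULP segment simply does not exist before
#' 2006).
#'
#' @param panel A panel tibble with a `segment` column (see
#'   [assign_segments()]).
#' @param segments Segments to include (default: all present except
#'   `"unassigned"`).
#' @param periods Periods to include (default: all present).
#' @param weights `"share"` (volume-share weighting, the default) or
#'   `"equal"` (unweighted mean — a sensitivity mode for price lists carrying
#'   no volume data).
#' @return A tibble `segment, period, wap` (pence per pack).
#' @export
weighted_average_price <- function(panel, segments = NULL, periods = NULL,
                                   weights = c("share", "equal")) {
  weights <- match.arg(weights)
  if (!"segment" %in% names(panel)) {
    abort("Panel has no segment column; run assign_segments() first.")
  }
  segments <- segments %||% setdiff(unique(panel$segment), "unassigned")
  periods <- periods %||% sort(unique(panel$period))
  rows <- panel |>
    dplyr::filter(.data$segment %in% segments, .data$period %in% periods)
  if (weights == "equal") rows$volume_share <- 1
  rows |>
    dplyr::filter(.data$volume_share > 0) |>
    dplyr::group_by(.data$segment, .data$period) |>
    dplyr::summarise(
      wap = sum(.data$volume_share * .data$nominal_price) /
        sum(.data$volume_share),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$segment, .data$period)
}

#' Volume market share by segment
#'
#' Whole-market share held by each segment in each period, plus an explicit
#' `"others"` row absorbing the share mass not attached to any listed brand
#' (one minus the panel's per-period share sum) together with any
#' `"unassigned"` brands. Shares plus others sum to 1 in every period.
#'
#' @param panel A panel tibble with a `segment` column.
#' @return A tibble `period, segment, share` including an `"others"` segment.
#' @export
segment_shares <- function(panel) {
  if (!"segment" %in% names(panel)) {
    abort("Panel has no segment column; run assign_segments() first.")
  }
  assigned <- panel |>
    dplyr::mutate(segment = ifelse(.data$segment == "unassigned", "others",
                                   .data$segment)) |>
    dplyr::group_by(.data$period, .data$segment) |>
    dplyr::summarise(share = sum(.data$volume_share), .groups = "drop")
  residual <- panel |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(share = 1 - sum(.data$volume_share), .groups = "drop") |>
    dplyr::mutate(segment = "others")
  dplyr::bind_rows(assigned, residual) |>
    dplyr::group_by(.data$period, .data$segment) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop") |>
    dplyr::arrange(.data$period, .data$segment)
}

#' Per-segment price, tax and net-of-tax revenue series
#'
#' The pipeline's central table: for every segment and period, the weighted
#' average price (WAP), the per-pack tax burden computed on that WAP under
#' the regime in force at the period's representative date, the net-of-tax
#' revenue (WAP minus tax), the CPI-deflated real counterparts, and the
#' segment's whole-market volume share. Tax is computed on the segment WAP —
#' not averaged over per-brand tax bills — matching how tax paid per pack is
#' conventionally derived from segment-level average prices.
#'
#' A pseudo-segment `"all"` (included by default) carries the whole-market
#' weighted average across every listed brand, the basis of the
#' "all brands" row of the shifting table.
#'
#' @param panel A panel tibble with `segment` assigned. Prices should already
#'   be normalised to `pack_size` sticks (see [normalize_pack()]).
#' @param schedule A [regime_schedule()].
#' @param cpi An [index_series()].
#' @param pack_size Sticks per pack used for the specific duty (default 20).
#' @param include_all Include the `"all"` pseudo-segment (default `TRUE`).
#' @param oct_2005 Passed to [period_date()].
#' @param weights Passed to [weighted_average_price()].
#' @return A tibble `segment, period, date, wap_nominal, wap_real, tax_total,
#'   net_revenue_nominal, net_revenue_real, segment_share`, satisfying
#'   `net_revenue_nominal = wap_nominal - tax_total` at every row.
#' @export
build_segment_series <- function(panel, schedule, cpi, pack_size = 20,
                                 include_all = TRUE, oct_2005 = FALSE,
                                 weights = "share") {
  wap <- weighted_average_price(panel, weights = weights)
  if (include_all) {
    all_wap <- panel |>
      dplyr::mutate(segment = "all") |>
      weighted_average_price(segments = "all", weights = weights)
    wap <- dplyr::bind_rows(wap, all_wap)
  }
  shares <- segment_shares(panel)
  all_share <- shares |>
    dplyr::filter(.data$segment != "others") |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(share = sum(.data$share), .groups = "drop") |>
    dplyr::mutate(segment = "all")
  shares <- dplyr::bind_rows(shares, all_share)

  wap$date <- period_date(wap$period, oct_2005 = oct_2005)
  tax <- purrr::map2_dbl(wap$wap, wap$date, function(p, d) {
    tax_breakdown(p, regime_at(schedule, d), pack_size = pack_size)$total
  })
  wap |>
    dplyr::mutate(
      wap_nominal = .data$wap,
      tax_total = tax,
      net_revenue_nominal = .data$wap_nominal - .data$tax_total,
      wap_real = deflate(.data$wap_nominal, .data$date, cpi),
      net_revenue_real = deflate(.data$net_revenue_nominal, .data$date, cpi)
    ) |>
    dplyr::left_join(shares, by = c("segment", "period")) |>
    dplyr::mutate(segment_share = dplyr::coalesce(.data$share, 0)) |>
    dplyr::select("segment", "period", "date", "wap_nominal", "wap_real",
                  "tax_total", "net_revenue_nominal", "net_revenue_real",
                  "segment_share") |>
    dplyr::arrange(.data$segment, .data$period)
}

#' Plot per-segment series
#'
#' Line plot of one measure from [build_segment_series()] by segment —
#' the analogue of the published real-price, market-share and net-revenue
#' trend figures.
#'
#' @param series A tibble from [build_segment_series()].
#' @param measure Column to plot (default `"wap_real"`).
#' @param include_all Keep the `"all"` pseudo-segment (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_segment_series <- function(series, measure = "wap_real",
                                include_all = FALSE) {
  if (!include_all) series <- dplyr::filter(series, .data$segment != "all")
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data$date, y = .data[[measure]], colour = .data$segment
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = measure, colour = "segment")
}
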