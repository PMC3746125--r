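#' Classify tax shifting from a net-of-tax real price change
#'
#' A positive change in real net-of-tax revenue per pack over a window
#' containing a duty increase means the industry raised prices by more than
#' the tax (overshifting); a negative change means part of the tax was
#' absorbed (undershifting); changes within `tol` of zero are full
#' pass-through.
#'
#' @param delta Net-of-tax real change(s), pence per pack.
#' @param tol Classification tolerance in pence (default 0.05, half the
#'   one-decimal reporting precision).
#' @return Character vector: `"overshift"`, `"full_shift"` or `"undershift"`.
#' @export
classify_shift <- function(delta, tol = 0.05) {
  dplyr::case_when(
    delta > tol ~ "overshift",
    delta < -tol ~ "undershift",
    TRUE ~ "full_shift"
  )
}

#' Net-of-tax real price change over a window
#'
#' For each segment present at both endpoints, the change in real net-of-tax
#' revenue per pack between two periods, classified with [classify_shift()].
#' When a regime schedule is supplied, `contains_duty_event` flags windows
#' with a specific-duty increase in `(from, to]` — the windows where
#' over/undershifting of a tax rise is meaningful.
#'
#' @param series A tibble from [build_segment_series()].
#' @param from_period,to_period Period labels bounding the window.
#' @param schedule Optional [regime_schedule()] used to flag duty events.
#' @param tol Passed to [classify_shift()].
#' @return A tibble `segment, from_period, to_period, delta_net_real,
#'   classification, contains_duty_event`.
#' @export
net_real_change <- function(series, from_period, to_period, schedule = NULL,
                            tol = 0.05) {
  ends <- lapply(c(from_period, to_period), function(p) {
    rows <- dplyr::filter(series, .data$period == p)
    if (nrow(rows) == 0) {
      abort(paste0("Period ", p, " is not present in the segment series."))
    }
    rows
  })
  joined <- dplyr::inner_join(
    ends[[1]], ends[[2]],
    by = "segment", suffix = c("_from", "_to")
  )
  duty_event <- if (is.null(schedule)) {
    NA
  } else {
    is_increase <- c(FALSE, diff(schedule$specific_duty) > 0)
    any(is_increase &
          schedule$effective_from > min(joined$date_from) &
          schedule$effective_from <= max(joined$date_to))
  }
  tibble(
    segment = joined$segment,
    from_period = from_period,
    to_period = to_period,
    delta_net_real = joined$net_revenue_real_to - joined$net_revenue_real_from,
    classification = classify_shift(
      joined$net_revenue_real_to - joined$net_revenue_real_from, tol
    ),
    contains_duty_event = duty_event
  )
}

#' Decompose a November-to-November year into half-year windows
#'
#' Annual duty increases fall in March or April, i.e. inside the
#' November-to-May window; May-to-November contains no duty event. The year
#' labelled `year` runs from `year`-H2 (November) to `year+1`-H2, split at
#' `year+1`-H1 (May/June). The two half-window changes sum exactly to the
#' annual change.
#'
#' @param series A tibble from [build_segment_series()].
#' @param year November start year of the window (the "2006" of "2006-07").
#' @inheritParams net_real_change
#' @return A tibble of [net_real_change()] rows with a `window` column taking
#'   values `"nov_may"`, `"may_nov"` and `"nov_nov"`, plus a `year` column.
#' @export
decompose_year <- function(series, year, schedule = NULL, tol = 0.05) {
  p0 <- period_label(year, "H2")
  p1 <- period_label(year + 1, "H1")
  p2 <- period_label(year + 1, "H2")
  dplyr::bind_rows(
    dplyr::mutate(net_real_change(series, p0, p1, schedule, tol),
                  window = "nov_may"),
    dplyr::mutate(net_real_change(series, p1, p2, schedule, tol),
                  window = "may_nov"),
    dplyr::mutate(net_real_change(series, p0, p2, schedule, tol),
                  window = "nov_nov")
  ) |>
    dplyr::mutate(year = year) |>
    dplyr::select("segment", "year", "window", dplyr::everything())
}

#' Multi-year average shifting by window type
#'
#' Averages the per-year net-of-tax real changes over a run of
#' November-labelled years, separately for the November-to-May (duty event),
#' May-to-November and full November-to-November windows. With
#' `use_rounded_years = TRUE` (the default) each yearly change is first
#' rounded to `digits` decimals, averaging the figures as they would appear
#' in a published table; internal full-precision averaging is available with
#' `use_rounded_years = FALSE`.
#'
#' @param series A tibble from [build_segment_series()].
#' @param years Integer vector of November start years.
#' @param use_rounded_years Round yearly changes to `digits` decimals before
#'   averaging (default `TRUE`).
#' @param digits Reporting precision (default 1 decimal of a penny).
#' @inheritParams net_real_change
#' @return A tibble `segment, window, average` (pence per pack per year,
#'   unrounded), plus `n_years`.
#' @export
multi_year_average <- function(series, years, schedule = NULL,
                               use_rounded_years = TRUE, digits = 1,
                               tol = 0.05) {
  stopifnot(length(years) >= 1)
  yearly <- dplyr::bind_rows(
    lapply(years, function(y) decompose_year(series, y, schedule, tol))
  )
  if (use_rounded_years) {
    yearly$delta_net_real <- round_report(yearly$delta_net_real, digits)
  }
  yearly |>
    dplyr::group_by(.data$segment, .data$window) |>
    dplyr::summarise(
      average = mean(.data$delta_net_real),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Shifting table: yearly and average net-of-tax real changes by segment
#'
#' The headline pass-through table: one row per segment with the yearly
#' November-to-November net-of-tax real price change for each year, and the
#' multi-year averages for the November-to-May (duty event), May-to-November
#' and November-to-November windows. Values are rounded half away from zero
#' to `digits` decimals; yearly columns are labelled by their November start,
#' e.g. `"2006-07"`.
#'
#' @inheritParams multi_year_average
#' @param digits Reporting precision; use `NULL` to leave values unrounded.
#' @return A wide tibble `segment, <year columns>, nov_may, may_nov, nov_nov`.
#' @export
shifting_table <- function(series, years, schedule = NULL,
                           use_rounded_years = TRUE, digits = 1, tol = 0.05) {
  yearly <- dplyr::bind_rows(
    lapply(years, function(y) decompose_year(series, y, schedule, tol))
  ) |>
    dplyr::filter(.data$window == "nov_nov") |>
    dplyr::mutate(col = paste0(.data$year, "-",
                               sprintf("%02d", (.data$year + 1) %% 100))) |>
    dplyr::select("segment", "col", "delta_net_real") |>
    tidyr::pivot_wider(names_from = "col", values_from = "delta_net_real")
  avgs <- multi_year_average(series, years, schedule, use_rounded_years,
                             digits = digits %||% 1, tol = tol) |>
    dplyr::select("segment", "window", "average") |>
    tidyr::pivot_wider(names_from = "window", values_from = "average")
  out <- dplyr::left_join(yearly, avgs, by = "segment") |>
    dplyr::relocate("segment") |>
    dplyr::relocate("nov_may", "may_nov", "nov_nov",
                    .after = dplyr::last_col())
  seg_order <- c("premium", "mid", "economy", "ulp", "all")
  out <- dplyr::arrange(
    out, match(.data$segment, seg_order, nomatch = length(seg_order) + 1)
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::where(is.numeric), ~ round_report(.x, digits)
    ))
  }
  out
}

#' Shifting analysis restricted to brands above a share threshold
#'
#' Re-runs the segment series and shifting table after dropping brands whose
#' whole-market volume share at the initial period is not strictly greater
#' than `min_share` — e.g. `min_share = 0.002` keeps brands with over 0.2% of
#' the market. A segment emptied by the filter simply disappears from the
#' result (reported as missing, not zero).
#'
#' @param panel A panel tibble with `segment` assigned.
#' @param min_share Share threshold in `[0, 1)`; brands with
#'   `share <= min_share` at `initial_period` are excluded (strict "over").
#' @param initial_period Period at which the filter is evaluated (default:
#'   `years[1]`-H2, the start of the analysis span).
#' @inheritParams build_segment_series
#' @inheritParams shifting_table
#' @return A list with the filtered `panel`, `series`, and `table`.
#' @export
filtered_shift <- function(panel, min_share, years, schedule, cpi,
                           initial_period = NULL, pack_size = 20,
                           use_rounded_years = TRUE, digits = 1, tol = 0.05,
                           oct_2005 = FALSE) {
  stopifnot(min_share >= 0, min_share < 1)
  initial_period <- initial_period %||% period_label(years[1], "H2")
  keep <- panel |>
    dplyr::filter(.data$period == initial_period,
                  .data$volume_share > min_share) |>
    dplyr::pull(.data$brand_id)
  sub <- dplyr::filter(panel, .data$brand_id %in% keep)
  if (nrow(sub) == 0) {
    abort(paste0("No brand exceeds min_share = ", min_share, " at ",
                 initial_period, "."))
  }
  series <- build_segment_series(sub, schedule, cpi, pack_size = pack_size,
                                 oct_2005 = oct_2005)
  tab <- shifting_table(series, years, schedule, use_rounded_years,
                        digits = digits, tol = tol)
  list(panel = sub, series = series, table = tab)
}
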