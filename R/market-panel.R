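#' Brand-level market panels
#'
#' A market panel is a tibble of brand-level semiannual observations with
#' columns `brand_id`, `period` (see [period_label()]), `nominal_price`
#' (pence per pack), `pack_size` (sticks), `volume_share` (fraction of total
#' market sticks) and `source` (a tag such as `"survey"` or `"scan"`).
#' Within each period the shares of listed brands must sum to at most 1; the
#' remainder is the "others" mass — brands that could not be identified or
#' priced — which is carried explicitly by [segment_shares()].
#'
#' `validate_panel()` checks the invariants and returns the panel (as a
#' tibble) or fails with row/period context.
#'
#' @param panel A data frame of brand observations.
#' @param share_tol Slack allowed on the per-period share sum (default 1e-9).
#' @return The validated panel as a tibble.
#' @export
validate_panel <- function(panel, share_tol = 1e-9) {
  required <- c("brand_id", "period", "nominal_price", "pack_size",
                "volume_share", "source")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("Panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  panel <- as_tibble(panel)
  check_period(panel$period)
  bad_price <- which(!is.finite(panel$nominal_price) | panel$nominal_price <= 0)
  if (length(bad_price) > 0) {
    abort(paste0("Non-positive or non-numeric nominal_price in row(s): ",
                 paste(head(bad_price, 5), collapse = ", ")))
  }
  bad_share <- which(!is.finite(panel$volume_share) | panel$volume_share < 0)
  if (length(bad_share) > 0) {
    abort(paste0("Negative or non-numeric volume_share in row(s): ",
                 paste(head(bad_share, 5), collapse = ", ")))
  }
  key <- paste(panel$brand_id, panel$period, panel$source, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate (brand_id, period, source) observation(s) in row(s): ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  sums <- tapply(panel$volume_share, panel$period, sum)
  over <- names(sums)[sums > 1 + share_tol]
  if (length(over) > 0) {
    abort(paste0(
      "volume_share sums exceed 1 in period(s): ",
      paste(over, " (", signif(sums[over], 4), ")", sep = "", collapse = ", ")
    ))
  }
  panel
}

#' Read and write market panels as CSV
#'
#' The CSV dialect has header
#' `brand_id,period,nominal_price,pack_size,volume_share,source`; lines
#' starting with `#` are comments (used for provenance headers). Reading
#' validates the panel and rejects files violating the panel invariants with
#' row numbers.
#'
#' @param path Path to a CSV file.
#' @return `read_panel()` returns a validated panel tibble.
#' @export
read_panel <- function(path) {
  hdr <- names(readr::read_csv(path, comment = "#", n_max = 0,
                               show_col_types = FALSE))
  required <- c("brand_id", "period", "nominal_price", "pack_size",
                "volume_share", "source")
  missing <- setdiff(required, hdr)
  if (length(missing) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- readr::read_csv(
    path,
    comment = "#",
    col_types = readr::cols(
      brand_id = readr::col_character(),
      period = readr::col_character(),
      nominal_price = readr::col_double(),
      pack_size = readr::col_double(),
      volume_share = readr::col_double(),
      source = readr::col_character()
    )
  )
  validate_panel(raw)
}

#' @rdname read_panel
#' @param panel A panel tibble.
#' @param header Optional character vector of comment lines written (prefixed
#'   with `#`) before the CSV.
#' @return `write_panel()` returns `path` invisibly.
#' @export
write_panel <- function(panel, path, header = NULL) {
  cols <- c("brand_id", "period", "nominal_price", "pack_size",
            "volume_share", "source")
  extra <- intersect("segment", names(panel))
  write_csv_with_header(panel[c(cols, extra)], path, header)
}

#' Normalise prices to a common pack size
#'
#' Brands sold in 19s are rescaled to the pack-of-20 price (or any `target`),
#' `price * target / pack_size`; the as-sold pack size is retained in
#' `pack_size_orig`. Idempotent.
#'
#' @param panel A panel tibble.
#' @param target Target sticks per pack (default 20).
#' @return The panel with `nominal_price` rescaled and `pack_size = target`.
#' @export
normalize_pack <- function(panel, target = 20) {
  if (any(panel$pack_size <= 0)) abort("pack_size must be positive.")
  if (!"pack_size_orig" %in% names(panel)) {
    panel$pack_size_orig <- panel$pack_size
  }
  dplyr::mutate(
    panel,
    nominal_price = .data$nominal_price * target / .data$pack_size,
    pack_size = target
  )
}

#' Brand-to-segment maps
#'
#' The industry groups brands into four price segments — premium, mid,
#' economy and ultra-low price (ULP) — the last sold by transnational
#' companies only from 2006. A segment map is a tibble with columns
#' `brand_id`, `segment` and optional `valid_from` / `valid_to` dates bounding
#' when the assignment applies. ULP entries default to a validity start of
#' 2006-01-01 when none is given.
#'
#' @param map A data frame with at least `brand_id` and `segment`.
#' @return A validated segment-map tibble with `valid_from` / `valid_to`
#'   columns (NA = unbounded).
#' @export
segment_map <- function(map) {
  segments <- c("premium", "mid", "economy", "ulp", "unassigned")
  missing <- setdiff(c("brand_id", "segment"), names(map))
  if (length(missing) > 0) {
    abort(paste0("Segment map is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  map <- as_tibble(map)
  bad <- setdiff(unique(map$segment), segments)
  if (length(bad) > 0) {
    abort(paste0("Unknown segment(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ", paste(segments, collapse = ", ")))
  }
  if (!"valid_from" %in% names(map)) map$valid_from <- as.Date(NA)
  if (!"valid_to" %in% names(map)) map$valid_to <- as.Date(NA)
  map$valid_from <- as.Date(map$valid_from)
  map$valid_to <- as.Date(map$valid_to)
  ulp_open <- map$segment == "ulp" & is.na(map$valid_from)
  map$valid_from[ulp_open] <- as.Date("2006-01-01")
  if (anyDuplicated(map$brand_id)) {
    # overlapping validity windows for one brand are ambiguous
    dup <- map |>
      dplyr::group_by(.data$brand_id) |>
      dplyr::filter(dplyr::n() > 1) |>
      dplyr::arrange(.data$valid_from, .by_group = TRUE) |>
      dplyr::summarise(overlap = any(
        head(dplyr::coalesce(.data$valid_to, as.Date("9999-12-31")), -1) >=
          tail(dplyr::coalesce(.data$valid_from, as.Date("0001-01-01")), -1)
      ))
    if (any(dup$overlap)) {
      abort(paste0("Overlapping validity windows for brand(s): ",
                   paste(dup$brand_id[dup$overlap], collapse = ", ")))
    }
  }
  map
}

#' @rdname segment_map
#' @param path Path to a CSV with columns
#'   `brand_id,segment,valid_from,valid_to` (the validity columns optional).
#' @export
read_segment_map <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  segment_map(raw)
}

#' Label panel observations with price segments
#'
#' Joins a [segment_map()] onto a panel by `brand_id`, respecting validity
#' windows evaluated at each observation's representative date. Brands absent
#' from the map — or mapped to a segment outside its validity window, e.g. a
#' ULP brand observed before 2006 — are labelled `"unassigned"`; their share
#' mass flows to the "others" bucket in [segment_shares()]. Total share mass
#' is conserved.
#'
#' @param panel A panel tibble.
#' @param map A [segment_map()] tibble.
#' @param oct_2005 Passed to [period_date()].
#' @return The panel with a `segment` column.
#' @export
assign_segments <- function(panel, map, oct_2005 = FALSE) {
  map <- segment_map(map)
  date <- period_date(panel$period, oct_2005 = oct_2005)
  seg <- rep("unassigned", nrow(panel))
  for (i in seq_len(nrow(map))) {
    hit <- panel$brand_id == map$brand_id[i] &
      (is.na(map$valid_from[i]) | date >= map$valid_from[i]) &
      (is.na(map$valid_to[i]) | date <= map$valid_to[i])
    seg[hit] <- map$segment[i]
  }
  out_of_window <- panel$brand_id %in% map$brand_id & seg == "unassigned"
  if (any(out_of_window)) {
    warn(paste0(
      "Observation(s) outside their segment validity window left unassigned: ",
      paste(unique(paste0(panel$brand_id, " @ ", panel$period)[out_of_window]),
            collapse = ", ")
    ))
  }
  panel$segment <- seg
  panel
}

#' Merge panels from multiple sources
#'
#' When no single data source covers the whole study span (e.g. hand-recorded
#' recommended retail prices early on, scan data later), panels are merged by
#' source precedence: for each `(brand_id, period)` the observation from the
#' highest-precedence source present is kept. Overlap observations displaced
#' by a higher-precedence source are returned in the `"overlap"` attribute so
#' cross-source consistency can be reported.
#'
#' @param panels A list of panel tibbles sharing the period convention.
#' @param precedence Character vector of source tags, highest precedence
#'   first. Sources not listed rank after all listed ones.
#' @return The merged panel tibble, with displaced overlap rows in
#'   `attr(, "overlap")`.
#' @export
merge_sources <- function(panels, precedence) {
  combined <- dplyr::bind_rows(lapply(panels, validate_panel))
  packs <- combined |>
    dplyr::group_by(.data$brand_id, .data$period) |>
    dplyr::filter(dplyr::n_distinct(.data$pack_size) > 1) |>
    dplyr::ungroup()
  if (nrow(packs) > 0) {
    abort(paste0(
      "Conflicting pack sizes for the same (brand, period) across sources: ",
      paste(unique(paste0(packs$brand_id, " @ ", packs$period)),
            collapse = ", "),
      ". Run normalize_pack() on each panel first."
    ))
  }
  rank <- match(combined$source, precedence)
  rank[is.na(rank)] <- length(precedence) + 1L
  combined$.rank <- rank
  kept <- combined |>
    dplyr::group_by(.data$brand_id, .data$period) |>
    dplyr::slice_min(.data$.rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  displaced <- dplyr::anti_join(
    combined, kept,
    by = c("brand_id", "period", "source")
  )
  kept$.rank <- NULL
  displaced$.rank <- NULL
  kept <- dplyr::arrange(kept, .data$period, .data$brand_id)
  out <- validate_panel(kept)
  attr(out, "overlap") <- displaced
  out
}

write_csv_with_header <- function(x, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}
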