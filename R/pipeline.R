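#' Read and write scenario configurations as YAML
#'
#' The scenario configuration is serialised as a nested key-value YAML file
#' so simulations are reproducible from a plain-text artefact.
#'
#' @param config A [scenario_config()].
#' @param path Output (or input) path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a validated `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(
    years = as.integer(range(config$years)),
    segments = lapply(seq_len(nrow(config$segments)), function(i) {
      as.list(config$segments[i, ])
    }),
    others_share = config$others_share,
    noise_sd = config$noise_sd,
    beta = config$beta,
    specific0 = config$specific0,
    duty_uplift = config$duty_uplift,
    ad_valorem = config$ad_valorem,
    vat_changes = lapply(seq_len(nrow(config$vat_changes)), function(i) {
      list(from = format(config$vat_changes$from[i]),
           rate = config$vat_changes$rate[i])
    }),
    cpi_annual = config$cpi_annual,
    cpi_base = format(config$cpi_base),
    pack_size = config$pack_size,
    seed = config$seed,
    price_spread = config$price_spread
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  segments <- dplyr::bind_rows(lapply(raw$segments, as_tibble))
  scenario_config(
    years = seq(raw$years[1], raw$years[2]),
    segments = segments,
    others_share = raw$others_share,
    noise_sd = raw$noise_sd,
    beta = raw$beta,
    specific0 = raw$specific0,
    duty_uplift = raw$duty_uplift,
    ad_valorem = raw$ad_valorem,
    vat_changes = tibble(
      from = as.Date(vapply(raw$vat_changes, `[[`, "", "from")),
      rate = vapply(raw$vat_changes, `[[`, 0, "rate")
    ),
    cpi_annual = raw$cpi_annual,
    cpi_base = raw$cpi_base,
    pack_size = raw$pack_size,
    seed = raw$seed,
    price_spread = raw$price_spread
  )
}

provenance_header <- function(seed, config_hash = NA) {
  c(
    paste0("taxshift ", as.character(utils::packageVersion("taxshift"))),
    paste0("seed: ", seed),
    paste0("config_hash: ", config_hash),
    paste0("written: deterministic content; header excluded from hashes")
  )
}

#' Simulate a market and write its artefacts to disk
#'
#' Generates a scenario with [simulate_market()] and writes `panel.csv`,
#' `segment_map.csv`, `cpi.csv`, `regimes.csv`, `ground_truth.csv` and
#' `scenario.yaml` into `out_dir`. Every CSV carries a provenance comment
#' header with the package version, seed and a hash of the configuration.
#'
#' @param config A [scenario_config()] (or path to a YAML written by
#'   [write_scenario_config()]).
#' @param out_dir Output directory.
#' @param create Create `out_dir` if absent (default `TRUE`).
#' @return Invisibly, a named character vector of the files written.
#' @export
run_simulate <- function(config, out_dir, create = TRUE) {
  if (is.character(config)) config <- read_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(out_dir)) {
    if (!create) abort(paste0("Output directory does not exist: ", out_dir))
    dir.create(out_dir, recursive = TRUE)
  }
  sim <- simulate_market(config)
  hdr <- provenance_header(config$seed, rlang::hash(unclass(config)))
  paths <- c(
    panel = file.path(out_dir, "panel.csv"),
    segment_map = file.path(out_dir, "segment_map.csv"),
    cpi = file.path(out_dir, "cpi.csv"),
    regimes = file.path(out_dir, "regimes.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    scenario = file.path(out_dir, "scenario.yaml")
  )
  write_panel(sim$panel, paths["panel"], header = hdr)
  write_csv_with_header(sim$map, paths["segment_map"], hdr)
  write_index_series(sim$cpi, paths["cpi"], header = hdr)
  write_regime_schedule(sim$schedule, paths["regimes"], header = hdr)
  write_csv_with_header(sim$ground_truth$realized, paths["ground_truth"], hdr)
  write_scenario_config(config, paths["scenario"])
  invisible(paths)
}

#' Run the full pricing analysis and write its reports to disk
#'
#' Reads the panel, segment map, regime schedule and CPI series, assigns
#' segments, builds the per-segment series, the shifting table, the index
#' comparison and the two brand-level scatter analyses, and writes
#' `segment_series.csv`, `shifting_table.csv`, `indices.csv` and
#' `scatters.csv` (plus `shifting_table_filtered.csv` when `min_share` is
#' set) into `out_dir`.
#'
#' @param panel Path to a panel CSV, or a panel tibble.
#' @param map Path to a segment-map CSV, or a [segment_map()] tibble.
#' @param regimes Path to a regime-schedule CSV, or a [regime_schedule()].
#' @param cpi Path to an index-series CSV, or an [index_series()].
#' @param out_dir Output directory.
#' @param years November start years for the shifting analysis (default: the
#'   span implied by the panel, minus the final year).
#' @param base_year Base month of the CPI series, e.g. `"2010-01-01"`
#'   (default: the series' own base).
#' @param min_share Optional share filter threshold for a second, filtered
#'   shifting table (strictly-greater-than filter at the initial period).
#' @param scatter_span Two period labels for the scatter analyses (default:
#'   first and last November of `years`).
#' @param external Optional external index series (path or [index_series()])
#'   for the index comparison.
#' @param pack_target Pack size to normalise to before analysis (default 20;
#'   `NULL` skips normalisation and uses as-sold pack prices).
#' @param create Create `out_dir` if absent.
#' @param use_rounded_years,digits,tol Passed to [shifting_table()].
#' @param oct_2005 Passed to [period_date()].
#' @return Invisibly, a list with the computed objects: `series`, `table`,
#'   `filtered_table` (or `NULL`), `indices`, `scatters`, and the file paths.
#' @export
run_analyze <- function(panel, map, regimes, cpi, out_dir,
                        years = NULL, base_year = NULL, min_share = NULL,
                        scatter_span = NULL, external = NULL,
                        pack_target = 20, create = TRUE,
                        use_rounded_years = TRUE, digits = 1, tol = 0.05,
                        oct_2005 = FALSE) {
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.character(map)) map <- read_segment_map(map)
  if (is.character(regimes)) regimes <- read_regime_schedule(regimes)
  if (is.character(cpi)) cpi <- read_index_series(cpi, base_month = base_year)
  if (!is.null(base_year)) cpi <- rebase_base_month(cpi, base_year)
  if (is.character(external)) external <- read_index_series(external)
  if (!dir.exists(out_dir)) {
    if (!create) abort(paste0("Output directory does not exist: ", out_dir))
    dir.create(out_dir, recursive = TRUE)
  }
  if (!is.null(pack_target)) panel <- normalize_pack(panel, pack_target)
  panel <- assign_segments(panel, map, oct_2005 = oct_2005)
  pack_size <- if (is.null(pack_target)) 20 else pack_target

  yrs_present <- sort(unique(period_year(panel$period)))
  years <- years %||% head(yrs_present, -1)
  series <- build_segment_series(panel, regimes, cpi, pack_size = pack_size,
                                 oct_2005 = oct_2005)
  tab <- shifting_table(series, years, regimes,
                        use_rounded_years = use_rounded_years,
                        digits = digits, tol = tol)
  cmp <- compare_indices(panel, external = external, oct_2005 = oct_2005)
  scatter_span <- scatter_span %||%
    c(period_label(min(years), "H2"), period_label(max(years) + 1, "H2"))
  sc1 <- price_change_vs_initial_share(panel, cpi, scatter_span[1],
                                       scatter_span[2], oct_2005 = oct_2005)
  sc2 <- share_change_vs_price_change(panel, cpi, scatter_span[1],
                                      scatter_span[2], oct_2005 = oct_2005)
  filtered <- if (!is.null(min_share)) {
    filtered_shift(panel, min_share, years, regimes, cpi,
                   pack_size = pack_size,
                   use_rounded_years = use_rounded_years, digits = digits,
                   tol = tol, oct_2005 = oct_2005)$table
  }

  hdr <- provenance_header(NA, rlang::hash(list(
    dim(panel), years, min_share, scatter_span
  )))
  paths <- c(
    segment_series = file.path(out_dir, "segment_series.csv"),
    shifting_table = file.path(out_dir, "shifting_table.csv"),
    indices = file.path(out_dir, "indices.csv"),
    scatters = file.path(out_dir, "scatters.csv")
  )
  write_csv_with_header(series, paths["segment_series"], hdr)
  write_csv_with_header(tab, paths["shifting_table"], hdr)
  indices_wide <- tidy(cmp) |>
    dplyr::select("period", "series", "index") |>
    tidyr::pivot_wider(names_from = "series", values_from = "index",
                       names_glue = "{series}_index")
  write_csv_with_header(indices_wide, paths["indices"], hdr)
  scatters <- dplyr::bind_rows(
    dplyr::mutate(tidy(sc1), analysis = "price_vs_initial_share"),
    dplyr::mutate(tidy(sc2), analysis = "share_change_vs_price_change")
  )
  write_csv_with_header(scatters, paths["scatters"], hdr)
  if (!is.null(filtered)) {
    paths["shifting_table_filtered"] <-
      file.path(out_dir, "shifting_table_filtered.csv")
    write_csv_with_header(filtered, paths["shifting_table_filtered"], hdr)
  }
  invisible(list(series = series, table = tab, filtered_table = filtered,
                 indices = cmp, scatters = list(sc1, sc2), paths = paths))
}

rebase_base_month <- function(cpi, base_year) {
  base <- as.Date(base_year)
  if (identical(index_base(cpi), snap_month(base))) return(cpi)
  index_series(cpi$month, cpi$value, base_month = base)
}
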