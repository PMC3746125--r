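#' Scenario configuration for the synthetic cigarette market
#'
#' Defines a synthetic brand-level market with known, controllable tax
#' pass-through. Each segment carries a duty-event effect `delta_event` (the
#' real net-of-tax pence added in each November-to-May window, which contains
#' the annual March/April duty increase) and an off-event `drift` (real pence
#' added per May-to-November window). Prices are generated by evolving each
#' brand's real net-of-tax revenue and inverting the tax engine
#' ([price_for_net_revenue()]) under the period's regime and CPI level — so
#' over- or undershifting by a configured amount is exact by construction,
#' not emergent. Gaussian noise (sd `noise_sd`, pence, on the net-revenue
#' scale) is added per brand and window from independent per-brand random
#' streams derived from the master seed, so adding a brand never perturbs
#' the others' trajectories.
#'
#' Volume shares follow a multiplicative logit drift: at each period brand
#' shares update as `w_b ∝ w_b_prev * exp(-beta * p_real_b / p_bar)`
#' with `p_bar` the share-weighted mean real price, then renormalise to the
#' listed-brand mass (1 minus `others_share`). Positive `beta` produces
#' downtrading — share flowing toward cheaper brands.
#'
#' @param years Calendar years spanned (semiannual periods H1/H2 each year).
#' @param segments A tibble with one row per segment: `segment`, `n_brands`,
#'   `price0` (nominal pence at entry), `entry_year`, `share0` (whole-market
#'   share at entry), `delta_event`, `drift` (real pence per window).
#' @param others_share Constant share mass held by unlisted brands.
#' @param noise_sd Noise sd on the net-revenue scale, pence, per window.
#' @param beta Downtrading sensitivity (0 = static shares).
#' @param specific0 Specific duty (pence per 1000) in force before the first
#'   modelled duty event.
#' @param duty_uplift Specific-duty increase per annual event, pence per 1000.
#' @param ad_valorem Ad valorem rate (constant across the span).
#' @param vat_changes Tibble `from` (Date), `rate`: VAT rate changes.
#' @param cpi_annual Annual CPI inflation rate.
#' @param cpi_base Base month of the CPI series (real pence are expressed in
#'   this month's money).
#' @param pack_size Sticks per pack.
#' @param seed Master seed; the whole scenario is deterministic given it.
#' @param price_spread Half-width of the deterministic relative spread of
#'   brand entry prices around `price0` within a segment.
#' @return A list with class `scenario_config`.
#' @seealso [default_uk_scenario()], [simulate_market()]
#' @export
scenario_config <- function(
    years = 2001:2009,
    segments = default_segments(),
    others_share = 0.10,
    noise_sd = 1,
    beta = 0.42,
    specific0 = 9225,
    duty_uplift = 275,
    ad_valorem = 0.22,
    vat_changes = tibble(
      from = as.Date(c("2000-01-01", "2008-12-01", "2010-01-01")),
      rate = c(0.175, 0.15, 0.175)
    ),
    cpi_annual = 0.02,
    cpi_base = "2010-01-01",
    pack_size = 20,
    seed = 42,
    price_spread = 0.02) {
  required <- c("segment", "n_brands", "price0", "entry_year", "share0",
                "delta_event", "drift")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0) {
    abort(paste0("segments is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  at_start <- segments$entry_year <= min(years)
  start_mass <- sum(segments$share0[at_start]) + others_share
  if (abs(start_mass - 1) > 1e-9) {
    abort(paste0("Initial shares (segments entering in ", min(years),
                 ") plus others_share must sum to 1; got ", start_mass, "."))
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (any(segments$price0 <= 0)) abort("Entry prices must be positive.")
  if (others_share < 0 || others_share >= 1) {
    abort("others_share must lie in [0, 1).")
  }
  structure(
    list(
      years = years, segments = as_tibble(segments),
      others_share = others_share, noise_sd = noise_sd, beta = beta,
      specific0 = specific0, duty_uplift = duty_uplift,
      ad_valorem = ad_valorem, vat_changes = as_tibble(vat_changes),
      cpi_annual = cpi_annual, cpi_base = as.Date(cpi_base),
      pack_size = pack_size, seed = as.integer(seed),
      price_spread = price_spread
    ),
    class = "scenario_config"
  )
}

default_segments <- function() {
  tibble(
    segment = c("premium", "mid", "economy", "ulp"),
    n_brands = c(4L, 3L, 5L, 4L),
    price0 = c(550, 500, 450, 400),
    entry_year = c(2001L, 2001L, 2001L, 2006L),
    share0 = c(0.30, 0.08, 0.52, 0.05),
    delta_event = c(2.9, 3.9, 2.1, -3.0),
    drift = c(1.2, 0.7, 2.8, 4.3)
  )
}

#' Default UK-style market scenario
#'
#' A 2001-2009 semiannual scenario mirroring the UK cigarette market's
#' structure: four price segments (premium/mid/economy/ULP) with ULP brands
#' entering in 2006; a specific duty rising from 9225 pence per 1000 sticks
#' by 275 pence each 1 April; a 22% ad valorem duty; VAT at 17.5%, cut to
#' 15% in December 2008 and restored to 17.5% in January 2010; 2% annual
#' CPI inflation with a 2010 base. Duty-event pass-through defaults are
#' overshifting on premium/mid/economy and absorption (undershifting) on
#' ULP, with compensating off-event increases on ULP; downtrading pressure
#' makes the ULP market share roughly double between 2006 and 2009.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_uk_scenario <- function(seed = 42, ...) {
  scenario_config(seed = seed, ...)
}

#' Downtrading scenario with a price-level-monotone growth gradient
#'
#' A variant of [default_uk_scenario()] configured so that real net-of-tax
#' price growth increases with segment price level: premium brands raise
#' prices fastest, ULP brands absorb duty increases and barely move. This is
#' the textbook downtrading configuration — the price gap widens while share
#' flows to the cheapest brands — and it is the scenario under which the
#' brand-level inverse relation between price change and market-share change
#' is the designed outcome. (In [default_uk_scenario()] the per-segment
#' changes follow the observed pattern where the economy segment shows the
#' largest increases, so the brand-level relation there is diluted by
#' economy brands gaining share despite fast price growth.)
#'
#' @inheritParams default_uk_scenario
#' @return A `scenario_config`.
#' @export
downtrading_scenario <- function(seed = 42, ...) {
  cfg <- default_uk_scenario(seed = seed, ...)
  cfg$segments$delta_event <- c(4, 3, 2, -3)
  cfg$segments$drift <- c(2, 1.5, 1, 1)
  cfg
}

#' Regime schedule implied by a scenario
#'
#' One regime per fiscal change: the pre-span baseline, each annual 1 April
#' duty uplift, and each VAT change, carrying forward the other parameters.
#'
#' @param config A [scenario_config()].
#' @return A [regime_schedule()].
#' @export
scenario_schedule <- function(config) {
  duty_dates <- as.Date(paste0(config$years, "-04-01"))
  changes <- dplyr::bind_rows(
    tibble(date = as.Date(paste0(min(config$years) - 1, "-04-01")),
           duty = config$specific0, vat = NA_real_),
    tibble(date = duty_dates,
           duty = config$specific0 + config$duty_uplift *
             seq_along(duty_dates),
           vat = NA_real_),
    tibble(date = config$vat_changes$from, duty = NA_real_,
           vat = config$vat_changes$rate)
  ) |>
    dplyr::arrange(.data$date) |>
    dplyr::mutate(
      duty = cummax_na(.data$duty, config$specific0),
      vat = last_obs(.data$vat, config$vat_changes$rate[1])
    ) |>
    dplyr::group_by(.data$date) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  regime_schedule(
    effective_from = changes$date,
    specific_duty = changes$duty,
    ad_valorem_rate = config$ad_valorem,
    vat_rate = changes$vat
  )
}

cummax_na <- function(x, init) {
  out <- x
  cur <- init
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cur <- max(cur, x[i])
    out[i] <- cur
  }
  out
}

last_obs <- function(x, init) {
  out <- x
  cur <- init
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cur <- x[i]
    out[i] <- cur
  }
  out
}

#' CPI series implied by a scenario
#'
#' A smooth monthly index compounding at the configured annual rate, spanning
#' the scenario years through the base month, with the base month at 100.
#'
#' @param config A [scenario_config()].
#' @return An [index_series()].
#' @export
scenario_cpi <- function(config) {
  months <- seq(as.Date(paste0(min(config$years) - 1, "-01-01")),
                max(config$cpi_base, as.Date(paste0(max(config$years) + 1,
                                                    "-12-01"))),
                by = "month")
  offset <- 12 * (as.integer(format(months, "%Y")) -
                    as.integer(format(config$cpi_base, "%Y"))) +
    (as.integer(format(months, "%m")) -
       as.integer(format(config$cpi_base, "%m")))
  values <- 100 * (1 + config$cpi_annual)^(offset / 12)
  index_series(months, values, base_month = config$cpi_base)
}

#' Generate a synthetic market panel with known pass-through
#'
#' Runs the generative model described in [scenario_config()]: brand-level
#' real net-of-tax revenues evolve by the segment's duty-event delta or
#' off-event drift plus noise; nominal prices are recovered through the exact
#' tax inverse under the dated regime schedule and CPI level; volume shares
#' follow the logit downtrading rule. Deterministic given the config seed.
#'
#' @param config A [scenario_config()].
#' @param realized Recompute the realized per-window ground truth from the
#'   emitted panel (default `TRUE`; switch off to generate many panels
#'   quickly when only the raw data are needed).
#' @return A list with class `market_sim`: `panel` (segment-assigned panel
#'   tibble), `map` (segment map), `schedule`, `cpi`, `ground_truth` (list:
#'   `configured` per-segment deltas, `realized` per-window net real changes
#'   recomputed from the emitted panel, `wap`, `shares`), and `config`.
#' @examples
#' sim <- simulate_market(default_uk_scenario(seed = 1))
#' head(sim$panel)
#' sim$ground_truth$configured
#' @export
simulate_market <- function(config, realized = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  schedule <- scenario_schedule(config)
  cpi <- scenario_cpi(config)
  span <- period_seq(min(config$years), max(config$years))
  dates <- period_date(span)
  # duty event in window (t-1, t]
  is_increase <- c(FALSE, diff(schedule$specific_duty) > 0)
  event_window <- vapply(seq_along(span)[-1], function(i) {
    any(is_increase & schedule$effective_from > dates[i - 1] &
          schedule$effective_from <= dates[i])
  }, logical(1))

  brands <- config$segments |>
    dplyr::rowwise() |>
    dplyr::reframe(
      segment = .data$segment,
      brand_id = paste0(.data$segment, "_", seq_len(.data$n_brands)),
      price0_b = .data$price0 *
        (1 + spread_offsets(.data$n_brands, config$price_spread)),
      w0 = entry_weights(.data$n_brands) * .data$share0,
      entry_year = .data$entry_year,
      delta_event = .data$delta_event,
      drift = .data$drift
    )
  brands$entry_idx <- match(period_label(pmax(brands$entry_year,
                                              min(config$years)), "H1"), span)

  n_b <- nrow(brands)
  n_p <- length(span)
  price <- matrix(NA_real_, n_b, n_p, dimnames = list(brands$brand_id, span))
  net_real <- matrix(NA_real_, n_b, n_p)
  base_cpi <- index_value_at(cpi, index_base(cpi))

  for (b in seq_len(n_b)) {
    e <- brands$entry_idx[b]
    noise <- brand_noise(config$seed, b, n_p, config$noise_sd)
    reg <- regime_at(schedule, dates[e])
    p0 <- brands$price0_b[b]
    nr <- deflate(tax_breakdown(p0, reg, config$pack_size)$net_revenue,
                  dates[e], cpi)
    price[b, e] <- p0
    net_real[b, e] <- nr
    if (e < n_p) {
      for (t in (e + 1):n_p) {
        step <- if (event_window[t - 1]) brands$delta_event[b] else
          brands$drift[b]
        nr <- nr + step + noise[t]
        net_nom <- nr * index_value_at(cpi, dates[t]) / base_cpi
        p <- price_for_net_revenue(net_nom, regime_at(schedule, dates[t]),
                                   config$pack_size)
        if (!is.finite(p) || p <= 0) {
          abort(paste0("Generated non-positive price for ",
                       brands$brand_id[b], " at ", span[t],
                       "; reduce the magnitude of negative deltas or noise."))
        }
        price[b, t] <- p
        net_real[b, t] <- nr
      }
    }
  }

  real_price <- sweep(price, 2,
                      index_value_at(cpi, dates) / base_cpi, "/")
  named_mass <- 1 - config$others_share
  share <- matrix(NA_real_, n_b, n_p, dimnames = list(brands$brand_id, span))
  active0 <- brands$entry_idx == 1
  share[active0, 1] <- brands$w0[active0] / sum(brands$w0[active0]) *
    named_mass
  for (t in 2:n_p) {
    prev_active <- !is.na(share[, t - 1])
    entering <- brands$entry_idx == t
    w_prev <- share[prev_active, t - 1]
    p_now <- real_price[prev_active, t]
    p_bar <- sum(w_prev / sum(w_prev) * p_now)
    w_raw <- w_prev * exp(-config$beta * p_now / p_bar)
    entrant_mass <- if (any(entering)) {
      # entrants take their configured whole-market mass from incumbents
      seg_mass <- config$segments$share0[match(
        unique(brands$segment[entering]), config$segments$segment
      )]
      sum(seg_mass)
    } else 0
    share[prev_active, t] <- w_raw / sum(w_raw) * (named_mass - entrant_mass)
    if (any(entering)) {
      share[entering, t] <- brands$w0[entering] / sum(brands$w0[entering]) *
        entrant_mass
    }
    if (any(share[, t] < 0, na.rm = TRUE)) {
      abort(paste0("Generated negative share at ", span[t], "."))
    }
  }

  obs <- which(!is.na(price), arr.ind = TRUE)
  panel <- tibble(
    brand_id = brands$brand_id[obs[, 1]],
    period = span[obs[, 2]],
    nominal_price = price[obs],
    pack_size = config$pack_size,
    volume_share = share[obs],
    source = "synthetic"
  ) |>
    dplyr::arrange(.data$period, .data$brand_id)
  map <- segment_map(tibble(
    brand_id = brands$brand_id,
    segment = brands$segment,
    valid_from = as.Date(paste0(brands$entry_year, "-01-01"))
  ))
  panel <- validate_panel(assign_segments(panel, map))

  ground_truth <- list(
    configured = dplyr::select(config$segments, "segment", "delta_event",
                               "drift"),
    realized = NULL,
    wap = NULL,
    shares = segment_shares(panel)
  )
  if (realized) {
    series <- build_segment_series(panel, schedule, cpi,
                                   pack_size = config$pack_size)
    rec_years <- seq(min(config$years), max(config$years) - 1)
    ground_truth$realized <- dplyr::bind_rows(
      lapply(rec_years, function(y) decompose_year(series, y, schedule))
    )
    ground_truth$wap <- dplyr::select(series, "segment", "period",
                                      "wap_nominal", "wap_real")
  }
  structure(
    list(panel = panel, map = map, schedule = schedule, cpi = cpi,
         ground_truth = ground_truth, config = config),
    class = "market_sim"
  )
}

spread_offsets <- function(n, half_width) {
  if (n == 1) return(0)
  seq(-half_width, half_width, length.out = n)
}

entry_weights <- function(n) {
  w <- seq(1.5, 0.5, length.out = n)
  w / sum(w)
}

brand_noise <- function(seed, brand_index, n, sd) {
  if (sd == 0) return(numeric(n))
  brand_seed <- as.integer((as.numeric(seed) * 1009 + brand_index * 7919) %%
                             2147483647)
  with_local_seed(brand_seed, rnorm(n, 0, sd))
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv()) else if (
      exists(".Random.seed", globalenv(), inherits = FALSE)
    ) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.market_sim <- function(x, ...) {
  cat("Synthetic cigarette market: ", min(x$config$years), "-",
      max(x$config$years), ", ", dplyr::n_distinct(x$panel$brand_id),
      " brands, seed ", x$config$seed, "\n", sep = "")
  print(x$ground_truth$configured)
  invisible(x)
}
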