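# Shared fixture builders: tiny panels, flat CPI, simple schedules.

flat_cpi <- function(value = 100, base = "2010-01-01") {
  months <- seq(as.Date("2000-01-01"), as.Date("2011-12-01"), by = "month")
  index_series(months, rep(value, length(months)), base_month = base)
}

zero_tax_schedule <- function() {
  regime_schedule("2000-01-01", 0, 0, 0)
}

regime_2009 <- function() {
  regime_schedule("2009-04-01", 11431, 0.24, 0.175)
}

# panel with explicit observation rows
make_panel <- function(brand_id, period, nominal_price, volume_share,
                       pack_size = 20, source = "test", segment = NULL) {
  p <- tibble::tibble(
    brand_id = brand_id, period = period, nominal_price = nominal_price,
    pack_size = pack_size, volume_share = volume_share, source = source
  )
  if (!is.null(segment)) p$segment <- segment
  validate_panel(p)
}

# two-segment, two-brand panel over a run of periods with constant prices
constant_panel <- function(periods = period_seq(2006, 2009)) {
  n <- length(periods)
  make_panel(
    brand_id = rep(c("a", "b"), each = n),
    period = rep(periods, 2),
    nominal_price = rep(c(500, 400), each = n),
    volume_share = rep(c(0.5, 0.4), each = n),
    segment = rep(c("premium", "economy"), each = n)
  )
}

# a segment series with prescribed real net revenue per period (one segment)
series_from_net_real <- function(periods, net_real, segment = "premium") {
  tibble::tibble(
    segment = segment,
    period = periods,
    date = period_date(periods),
    wap_nominal = NA_real_,
    wap_real = NA_real_,
    tax_total = NA_real_,
    net_revenue_nominal = NA_real_,
    net_revenue_real = net_real,
    segment_share = NA_real_
  )
}

# independent Spearman oracle: ranks by pairwise counting, classic formula
# (valid for untied data only)
spearman_oracle <- function(x, y) {
  rank_of <- function(v) {
    vapply(seq_along(v), function(i) 1 + sum(v < v[i]), numeric(1))
  }
  d <- rank_of(x) - rank_of(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# noiseless, driftless scenario with static shares; by default every
# segment (including ULP) is present from the start so even the market
# aggregate is composition-stable
null_scenario <- function(seed = 1, ulp_entry = 2001L) {
  cfg <- default_uk_scenario(seed = seed, noise_sd = 0, beta = 0)
  cfg$segments$delta_event <- 0
  cfg$segments$drift <- 0
  cfg$segments$entry_year[cfg$segments$segment == "ulp"] <- ulp_entry
  if (ulp_entry <= 2001L) {
    # ULP now claims its share from the start; rebalance to sum to one
    cfg$segments$share0 <- c(0.28, 0.08, 0.49, 0.05)
  }
  cfg
}

random_regime <- function() {
  repeat {
    a <- runif(1, 0, 0.5)
    v <- runif(1, 0, 0.3)
    if (a + v / (1 + v) < 0.95) break
  }
  regime_schedule(
    effective_from = as.Date("2000-01-01"),
    specific_duty = runif(1, 0, 15000),
    ad_valorem_rate = a,
    vat_rate = v
  )
}
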