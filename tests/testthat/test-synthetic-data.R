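test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_market(default_uk_scenario(seed = 9), realized = FALSE)
  b <- simulate_market(default_uk_scenario(seed = 9), realized = FALSE)
  expect_equal(a$panel, b$panel)
  # byte-identical CSV output
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_panel(a$panel, fa)
  write_panel(b$panel, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed produces different prices
  c_ <- simulate_market(default_uk_scenario(seed = 10), realized = FALSE)
  expect_false(identical(a$panel$nominal_price, c_$panel$nominal_price))
})

test_that("per-brand noise streams are stable when brands are added", {
  cfg_small <- default_uk_scenario(seed = 4)
  cfg_big <- default_uk_scenario(seed = 4)
  cfg_big$segments$n_brands[cfg_big$segments$segment == "ulp"] <- 6L
  small <- simulate_market(cfg_small, realized = FALSE)$panel
  big <- simulate_market(cfg_big, realized = FALSE)$panel
  # brands ordered before the enlarged segment keep identical price paths
  for (id in c("premium_1", "mid_2", "economy_5")) {
    expect_equal(big$nominal_price[big$brand_id == id],
                 small$nominal_price[small$brand_id == id])
  }
})

test_that("shares are conserved at every period", {
  sim <- simulate_market(default_uk_scenario(seed = 6), realized = FALSE)
  sums <- tapply(sim$panel$volume_share, sim$panel$period, sum)
  expect_equal(as.vector(sums),
               rep(1 - sim$config$others_share, length(sums)),
               tolerance = 1e-9)
})

test_that("the default scenario mirrors the UK market structure", {
  cfg <- default_uk_scenario(seed = 2)
  sched <- scenario_schedule(cfg)
  # VAT cut to 15% dated December 2008, restored at 17.5% in January 2010
  dec08 <- sched[sched$effective_from == as.Date("2008-12-01"), ]
  expect_equal(dec08$vat_rate, 0.15)
  jan10 <- sched[sched$effective_from == as.Date("2010-01-01"), ]
  expect_equal(jan10$vat_rate, 0.175)
  # annual duty uplifts each 1 April
  aprils <- sched$effective_from[format(sched$effective_from, "%m-%d") ==
                                   "04-01"]
  expect_setequal(as.integer(format(aprils, "%Y")), 2000:2009)

  sim <- simulate_market(cfg, realized = FALSE)
  # ULP observations absent before 2006; four segments from 2006 onward
  ulp <- sim$panel[sim$panel$segment == "ulp", ]
  expect_true(all(period_year(ulp$period) >= 2006))
  seg06 <- unique(sim$panel$segment[sim$panel$period == "2006-H2"])
  expect_setequal(seg06, c("premium", "mid", "economy", "ulp"))
  seg01 <- unique(sim$panel$segment[sim$panel$period == "2001-H1"])
  expect_setequal(seg01, c("premium", "mid", "economy"))
  # ULP market share roughly doubles over 2006-2009
  sh <- sim$ground_truth$shares
  ratio <- sh$share[sh$segment == "ulp" & sh$period == "2009-H2"] /
    sh$share[sh$segment == "ulp" & sh$period == "2006-H2"]
  expect_gt(ratio, 1.5)
})

test_that("a noiseless null scenario is exactly flat downstream", {
  # with every segment present from the start the whole market is flat too
  cfg <- null_scenario(seed = 1)
  sim <- simulate_market(cfg)
  r <- sim$ground_truth$realized
  expect_equal(max(abs(r$delta_net_real)), 0, tolerance = 1e-8)
  expect_true(all(r$classification == "full_shift"))
  # real net-of-tax revenue constant for every segment and the aggregate
  # (real gross prices still move as the nominal duty and VAT change)
  series <- build_segment_series(sim$panel, sim$schedule, sim$cpi)
  spread <- tapply(series$net_revenue_real, series$segment,
                   function(x) diff(range(x)))
  expect_equal(max(spread), 0, tolerance = 1e-8)

  # with the default mid-span ULP entry the named segments stay flat while
  # the market aggregate moves only by composition at entry
  cfg2 <- null_scenario(seed = 1, ulp_entry = 2006L)
  r2 <- simulate_market(cfg2)$ground_truth$realized
  segs <- r2[r2$segment != "all", ]
  expect_equal(max(abs(segs$delta_net_real)), 0, tolerance = 1e-8)
  allr <- r2[r2$segment == "all" & r2$year != 2005, ]
  expect_equal(max(abs(allr$delta_net_real)), 0, tolerance = 1e-8)
})

test_that("configured pass-through is reproduced exactly without noise", {
  cfg <- default_uk_scenario(seed = 1, noise_sd = 0, beta = 0)
  cfg$segments$delta_event <- c(4, 4, 4, -3)
  cfg$segments$drift <- 0
  sim <- simulate_market(cfg)
  r <- sim$ground_truth$realized
  nov_may <- r[r$window == "nov_may" & r$year >= 2006 &
                 r$segment %in% c("premium", "ulp"), ]
  expect_equal(
    nov_may$delta_net_real,
    ifelse(nov_may$segment == "premium", 4, -3),
    tolerance = 1e-8
  )
  expect_true(all(
    nov_may$classification[nov_may$segment == "premium"] == "overshift"
  ))
  expect_true(all(
    nov_may$classification[nov_may$segment == "ulp"] == "undershift"
  ))
})

test_that("configured deltas are recovered from a noisy default scenario", {
  cfg <- default_uk_scenario(seed = 42)
  sim <- simulate_market(cfg)
  r <- sim$ground_truth$realized
  r <- r[r$year %in% 2006:2008 & r$segment != "all", ]
  est <- dplyr::summarise(
    dplyr::group_by(r, segment, window),
    mean_delta = mean(delta_net_real), .groups = "drop"
  )
  truth <- cfg$segments
  n_events <- 3
  tol <- 3 * cfg$noise_sd / sqrt(n_events)
  for (i in seq_len(nrow(truth))) {
    seg <- truth$segment[i]
    got_event <- est$mean_delta[est$segment == seg & est$window == "nov_may"]
    got_drift <- est$mean_delta[est$segment == seg & est$window == "may_nov"]
    expect_lt(abs(got_event - truth$delta_event[i]), tol)
    expect_lt(abs(got_drift - truth$drift[i]), tol)
  }
})

test_that("impossible configurations fail loudly", {
  expect_error(default_uk_scenario(others_share = 1.0), "others_share")
  bad <- default_segments()
  bad$share0 <- c(0.5, 0.5, 0.5, 0.05)
  expect_error(scenario_config(segments = bad), "sum to 1")
  expect_error(scenario_config(noise_sd = -1), "noise_sd")
  # a catastrophic negative drift drives prices negative and is refused
  cfg <- default_uk_scenario(seed = 1, noise_sd = 0)
  cfg$segments$drift <- -200
  expect_error(simulate_market(cfg), "non-positive price")
})
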