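test_that("net real change classifies over/full/undershifting", {
  periods <- c("2006-H2", "2007-H1", "2007-H2")
  s <- series_from_net_real(periods, c(100, 100, 105))
  same <- net_real_change(s, "2006-H2", "2007-H1")
  expect_equal(same$delta_net_real, 0)
  expect_equal(same$classification, "full_shift")
  up <- net_real_change(s, "2007-H1", "2007-H2")
  expect_equal(up$delta_net_real, 5)
  expect_equal(up$classification, "overshift")
  down <- net_real_change(series_from_net_real(periods, c(100, 99, 99)),
                          "2006-H2", "2007-H1")
  expect_equal(down$classification, "undershift")
  # classification boundary sits at tol
  expect_equal(classify_shift(c(0.05, 0.0500001, -0.05, -0.051)),
               c("full_shift", "overshift", "full_shift", "undershift"))
  expect_error(net_real_change(s, "2005-H2", "2007-H1"), "2005-H2")
})

test_that("duty events are flagged from the schedule", {
  sched <- regime_schedule(
    effective_from = as.Date(c("2006-04-01", "2007-04-01")),
    specific_duty = c(10000, 10275),
    ad_valorem_rate = 0.22, vat_rate = 0.175
  )
  s <- series_from_net_real(c("2006-H2", "2007-H1", "2007-H2"),
                            c(100, 101, 102))
  # Nov-May window contains the April 2007 uplift; May-Nov does not
  expect_true(net_real_change(s, "2006-H2", "2007-H1",
                              sched)$contains_duty_event)
  expect_false(net_real_change(s, "2007-H1", "2007-H2",
                               sched)$contains_duty_event)
})

test_that("half-year decomposition adds exactly to the annual change", {
  # ULP-style year: -3.0 in Nov-May, +4.3 in May-Nov, 1.3 over the year
  s <- series_from_net_real(c("2006-H2", "2007-H1", "2007-H2"),
                            c(100, 97, 101.3), segment = "ulp")
  d <- decompose_year(s, 2006)
  delta <- setNames(d$delta_net_real, d$window)
  expect_equal(unname(delta["nov_may"]), -3.0)
  expect_equal(unname(delta["may_nov"]), 4.3)
  expect_equal(unname(delta["nov_nov"]), 1.3)
  expect_equal(delta[["nov_may"]] + delta[["may_nov"]], delta[["nov_nov"]])

  # premium-style year: 2.9 + 1.2 = 4.1
  s2 <- series_from_net_real(c("2006-H2", "2007-H1", "2007-H2"),
                             c(100, 102.9, 104.1))
  d2 <- decompose_year(s2, 2006)
  expect_equal(setNames(d2$delta_net_real, d2$window),
               c(nov_may = 2.9, may_nov = 1.2, nov_nov = 4.1))

  # a flat series decomposes to zeros
  d0 <- decompose_year(series_from_net_real(
    c("2006-H2", "2007-H1", "2007-H2"), rep(50, 3)), 2006)
  expect_equal(d0$delta_net_real, rep(0, 3))
  expect_error(decompose_year(s, 2007), "2008-H1")
})

test_that("decomposition additivity holds on simulated panels", {
  for (seed in c(11, 12)) {
    sim <- simulate_market(default_uk_scenario(seed = seed))
    r <- sim$ground_truth$realized
    wide <- tidyr::pivot_wider(
      r[, c("segment", "year", "window", "delta_net_real")],
      names_from = "window", values_from = "delta_net_real"
    )
    expect_equal(wide$nov_may + wide$may_nov, wide$nov_nov,
                 tolerance = 1e-9)
  }
})

test_that("multi-year averages mirror reporting arithmetic", {
  # premium-style yearly changes 4.6, 2.2, 5.7: cumulative path
  net <- c(100, 104.6, 106.8, 112.5)
  s <- series_from_net_real(c("2006-H2", "2007-H2", "2008-H2", "2009-H2"),
                            net)
  # insert the H1 midpoints so each year decomposes
  h1 <- series_from_net_real(c("2007-H1", "2008-H1", "2009-H1"),
                             c(102, 105, 110))
  s <- dplyr::arrange(dplyr::bind_rows(s, h1), period)
  avg <- multi_year_average(s, 2006:2008)
  nn <- avg$average[avg$window == "nov_nov"]
  expect_equal(nn, mean(c(4.6, 2.2, 5.7)), tolerance = 1e-9)
  expect_lt(abs(nn - 4.1), 0.07)

  # ULP-style yearly changes 4.8, -3.6, 2.8 average to 1.3
  net_u <- c(100, 104.8, 101.2, 104.0)
  su <- dplyr::bind_rows(
    series_from_net_real(c("2006-H2", "2007-H2", "2008-H2", "2009-H2"),
                         net_u, segment = "ulp"),
    series_from_net_real(c("2007-H1", "2008-H1", "2009-H1"),
                         c(101, 103, 102), segment = "ulp")
  )
  avg_u <- multi_year_average(su, 2006:2008)
  expect_equal(avg_u$average[avg_u$window == "nov_nov"],
               mean(c(4.8, -3.6, 2.8)), tolerance = 1e-9)
  expect_equal(round_report(avg_u$average[avg_u$window == "nov_nov"]), 1.3)

  # a single year returns that year's change
  one <- multi_year_average(s, 2006)
  expect_equal(one$average[one$window == "nov_nov"], 4.6)

  # rounded-years mode averages the one-decimal figures as printed; with
  # yearly changes of 4.25 the printed figures are 4.3 each
  quarter <- dplyr::bind_rows(
    series_from_net_real(c("2006-H2", "2007-H2", "2008-H2", "2009-H2"),
                         c(100, 104.25, 108.5, 112.75)),
    series_from_net_real(c("2007-H1", "2008-H1", "2009-H1"),
                         c(102, 106, 110))
  )
  rounded <- multi_year_average(quarter, 2006:2008, use_rounded_years = TRUE)
  full <- multi_year_average(quarter, 2006:2008, use_rounded_years = FALSE)
  expect_equal(rounded$average[rounded$window == "nov_nov"], 4.3)
  expect_equal(full$average[full$window == "nov_nov"], 4.25)
})

test_that("full pass-through everywhere yields only full_shift", {
  sim <- simulate_market(null_scenario(seed = 5))
  expect_true(all(sim$ground_truth$realized$classification == "full_shift"))
  expect_equal(max(abs(sim$ground_truth$realized$delta_net_real)), 0,
               tolerance = 1e-8)
})

test_that("share filter drops small brands strictly at the threshold", {
  periods <- c("2006-H2", "2007-H1", "2007-H2")
  p <- make_panel(
    brand_id = rep(c("big", "tiny"), each = 3),
    period = rep(periods, 2),
    nominal_price = c(500, 505, 510, 300, 300, 300),
    volume_share = rep(c(0.5, 0.002), each = 3),
    segment = "economy"
  )
  sched <- zero_tax_schedule()
  cpi <- flat_cpi()
  # min_share = 0 keeps everything: same table as unfiltered
  unfiltered <- shifting_table(build_segment_series(p, sched, cpi), 2006,
                               sched)
  f0 <- filtered_shift(p, 0, 2006, sched, cpi)
  expect_equal(f0$table, unfiltered)
  # threshold exactly at the tiny brand's share excludes it (strict "over")
  f <- filtered_shift(p, 0.002, 2006, sched, cpi)
  expect_equal(unique(f$panel$brand_id), "big")
  # removing the cheap tiny brand moves the WAP to the big brand's price
  expect_equal(
    f$series$wap_nominal[f$series$segment == "economy" &
                           f$series$period == "2006-H2"], 500
  )
  # a filter that empties the market errors
  expect_error(filtered_shift(p, 0.9, 2006, sched, cpi), "min_share")
})

test_that("shifting table has the reporting layout and rounding", {
  sim <- simulate_market(default_uk_scenario(seed = 8))
  series <- build_segment_series(sim$panel, sim$schedule, sim$cpi)
  tab <- shifting_table(series, 2006:2008, sim$schedule)
  expect_equal(names(tab), c("segment", "2006-07", "2007-08", "2008-09",
                             "nov_may", "may_nov", "nov_nov"))
  expect_equal(tab$segment,
               c("premium", "mid", "economy", "ulp", "all"))
  # one-decimal reporting
  expect_equal(tab$`2006-07`, round_report(tab$`2006-07`, 1))
})
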