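test_that("tax breakdown matches hand-computed components", {
  # zero-tax identity
  z <- tax_breakdown(500, zero_tax_schedule())
  expect_equal(z$total, 0)
  expect_equal(z$net_revenue, 500)

  # 2009-style mixed regime, each component from its closed form
  b <- tax_breakdown(500, regime_2009(), pack_size = 20)
  expect_equal(b$specific, 11431 * 20 / 1000)          # 228.62
  expect_equal(b$ad_valorem, 0.24 * 500)               # 120.00
  expect_equal(b$vat, 500 * 0.175 / 1.175)             # 74.468...
  expect_equal(b$total, b$specific + b$ad_valorem + b$vat)
  expect_equal(b$net_revenue, 500 - b$total)
  expect_equal(round(b$net_revenue, 2), 76.91)

  # VAT-only: vat extracted from the tax-inclusive price
  v <- tax_breakdown(100, regime_schedule("2000-01-01", 0, 0, 0.20))
  expect_equal(v$vat, 100 * 0.2 / 1.2)
  expect_equal(v$net_revenue, 100 - 100 * 0.2 / 1.2)

  expect_error(tax_breakdown(-1, regime_2009()), "positive")
  expect_error(tax_breakdown(0, regime_2009()), "positive")
})

test_that("price_for_net_revenue inverts the breakdown", {
  expect_equal(price_for_net_revenue(500, zero_tax_schedule()), 500)
  # round trip of the 2009-style example
  p <- price_for_net_revenue(76.91, regime_2009())
  expect_equal(tax_breakdown(p, regime_2009())$net_revenue, 76.91,
               tolerance = 1e-9)
  expect_equal(p, 500, tolerance = 1e-4)
  # specific duty only: price covers exactly the duty
  r <- regime_schedule("2000-01-01", 100, 0, 0)
  expect_equal(price_for_net_revenue(0, r, pack_size = 20), 2.0)
})

test_that("specific share of the tax burden", {
  only_spec <- tax_breakdown(500, regime_schedule("2000-01-01", 1000, 0, 0))
  expect_equal(specific_share(only_spec), 1.0)

  b <- tax_breakdown(500, regime_2009())
  expect_equal(specific_share(b), 228.62 / (228.62 + 120 + 500 * 0.175 / 1.175),
               tolerance = 1e-12)
  expect_equal(round(specific_share(b), 3), 0.54)

  no_spec <- tax_breakdown(500, regime_schedule("2000-01-01", 0, 0.2, 0))
  expect_equal(specific_share(no_spec), 0.0)
  expect_error(specific_share(tax_breakdown(500, zero_tax_schedule())),
               "undefined")
})

test_that("regime lookup is inclusive at the effective date", {
  sched <- regime_schedule(
    effective_from = as.Date(c("2008-04-01", "2009-04-01")),
    specific_duty = c(11000, 11431),
    ad_valorem_rate = 0.24, vat_rate = 0.175
  )
  expect_equal(regime_at(sched, "2009-04-01")$specific_duty, 11431)
  expect_equal(regime_at(sched, "2008-12-25")$specific_duty, 11000)
  expect_error(regime_at(sched, "2007-01-01"), "starts at 2008-04-01")
})

test_that("a regime taxing away all revenue is rejected at construction", {
  expect_error(regime_schedule("2000-01-01", 0, 0.9, 0.25), "non-positive")
  expect_error(regime_schedule("2000-01-01", -5, 0.2, 0.175), ">= 0")
  expect_error(
    regime_schedule(as.Date(c("2001-01-01", "2000-01-01")),
                    c(100, 100), 0.2, 0.175),
    "strictly increasing"
  )
})

test_that("randomized regimes satisfy round-trip, additivity and monotonicity", {
  set.seed(101)
  for (i in 1:200) {
    r <- random_regime()
    p <- runif(1, 50, 1200)
    b <- tax_breakdown(p, r)
    # additivity
    expect_equal(b$total, b$specific + b$ad_valorem + b$vat, tolerance = 1e-12)
    expect_equal(b$net_revenue + b$total, p, tolerance = 1e-9)
    # VAT extraction: rate applied to the pre-VAT price reproduces vat
    expect_equal((p - b$vat) * r$vat_rate, b$vat, tolerance = 1e-9)
    # round trip
    expect_equal(price_for_net_revenue(b$net_revenue, r), p,
                 tolerance = 1e-6)
    # monotonicity of net revenue in price
    b2 <- tax_breakdown(p + 1, r)
    expect_gt(b2$net_revenue, b$net_revenue)
  }
  # specific_share strictly increasing in specific duty at fixed price
  shares <- vapply(c(1000, 5000, 9000), function(sd) {
    specific_share(tax_breakdown(500, regime_schedule("2000-01-01", sd,
                                                      0.2, 0.175)))
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("regime schedules round-trip through CSV", {
  sched <- regime_schedule(
    effective_from = as.Date(c("2008-04-01", "2008-12-01")),
    specific_duty = c(11200, 11200),
    ad_valorem_rate = 0.22,
    vat_rate = c(0.175, 0.15)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_regime_schedule(sched, path, header = "fixture")
  back <- read_regime_schedule(path)
  expect_equal(as.data.frame(back), as.data.frame(sched))
})
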