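test_that("straight-line depreciation divides the depreciable base over life", {
  # cow convention: $1,200 purchase, $782.65 salvage, 10 yr
  expect_equal(straight_line_depreciation(1200, 782.65, 10), 41.735)
  expect_equal(straight_line_depreciation(500, 500, 7), 0)
  # bull convention: $3,060 purchase over a 5-yr service period
  bull_salvage <- (634.92 / 0.70) * 1.36
  expect_equal(straight_line_depreciation(3060, bull_salvage, 5),
               (3060 - bull_salvage) / 5)
  expect_error(straight_line_depreciation(100, 200, 5), "appreciation")
  expect_error(straight_line_depreciation(100, 50, 0), "positive")
})

test_that("cull schedule encodes the retention discount and bull share", {
  cs <- cull_schedule()
  expect_equal(1 - cs$retention_rate, 0.6793)
  expect_equal(cs$bull_share, 1 / 125)
  expect_equal(cs$prob_cull(5), 0)
  expect_equal(cs$prob_cull(11), 1)
  cs2 <- cull_schedule(involuntary_rate = 0.05)
  expect_equal(cs2$prob_cull(3), 0.05)
})

test_that("expected revenue decomposes into calf, cull cow and bull shares", {
  py <- list(steer_price = 3.20, heifer_price = 2.94,
             cull_cow_price = 1.22, cull_bull_price = 1.36)
  culls <- cull_schedule()
  r <- expected_revenue(250, 235, 540, 5, py, culls)
  expect_equal(r$steer, 0.5 * 250 * 3.20)
  expect_equal(r$heifer, 0.5 * 235 * 2.94 * 0.6793)
  expect_equal(r$cull_cow, 0)          # no cull before the cull age
  expect_equal(r$cull_bull, (540 / 0.70) * 1.36 / 125)
  expect_equal(r$total, r$steer + r$heifer + r$cull_cow + r$cull_bull)

  # at the cull age the cow's salvage weight enters at the cull price
  r2 <- expected_revenue(250, 235, 540, 11, py, culls)
  expect_equal(r2$cull_cow, 540 * 1.22)

  # degenerate schedule: calf revenue only
  none <- cull_schedule(cows_per_bull = Inf, involuntary_rate = 0)
  r3 <- expected_revenue(250, 235, 540, 5, py, none)
  expect_equal(r3$total, r3$steer + r3$heifer)

  # literal weighting toggle ties the heifer term to the cull probability
  r4 <- expected_revenue(250, 235, 540, 5, py, culls,
                         literal_heifer_cull = TRUE)
  expect_equal(r4$heifer, 0)
})

test_that("feed cost is land rent on the footprint plus hay at the short-ton
           conversion, and is linear in the footprint", {
  fc <- feed_cost(0.8, 74.07, 1636.52, 177)
  expect_equal(fc, 74.07 * 0.8 + 1636.52 * 177 / 907.185)
  expect_equal(feed_cost(0.8, 74.07, 0, 177), 74.07 * 0.8)
  expect_equal(feed_cost(1.6, 74.07, 0, 177), 2 * feed_cost(0.8, 74.07, 0, 177))
  # metric-tonne convention as a config flag
  expect_equal(feed_cost(0, 0, 1000, 200, ton_kg = 1000), 200)
})

test_that("cost schedules load, look up by year, and extend the projection
           rules past the last tabulated year", {
  hist <- cost_schedule("historical")
  expect_equal(hist$hay_ton[hist$year == 2018], 177.00)
  expect_equal(cost_year(hist, 2014)$feed_land_ha, 74.07)

  proj <- cost_schedule("projected")
  expect_equal(cost_year(proj, 2021)$hay_ton, 240.63)
  expect_error(cost_year(proj, 2010), "configuration")

  ext <- cost_year(proj, 2028)
  expect_equal(ext$mineral_cow, 38.98 * 1.01)
  expect_equal(ext$feed_land_ha, 69.13)     # land static
  expect_equal(ext$pasture_care_ha, 24.49)  # pasture care static
  expect_equal(ext$hay_ton, 354.71)         # hay carried forward
  expect_gt(ext$labor_wage_hr, 18.16)       # wage keeps its mean growth
})

test_that("the enterprise budget reproduces an independent hand-computed
           2018 budget to the cent", {
  # tier-4 cow (510 kg), age 6, 2018 prices and costs, spreadsheet-style
  dbw <- 510; age <- 6
  ir <- seasonal_intake(dbw, season_plan(200), forage_spec())
  steer_ww <- 250; heifer_ww <- 235

  # --- oracle: every line from the cost table and stated rules ---
  ha <- (200 * oracle_dmi_lact(dbw, 1.43, 8)) / (5662 * 0.5)
  hay_kg <- (49 + 115 * 1.05) * oracle_dmi_dry(dbw, 1.20)
  revenue <- 0.5 * 250 * 3.20 +                      # steer calf
    0.5 * 235 * 2.94 * 0.6793 +                      # heifer calf, retained
    0 +                                              # no cull at age 6
    (510 / 0.70) * 1.36 * (1 / 125)                  # bull salvage share
  feed <- 74.07 * ha + hay_kg * 177.00 / 907.185
  var_sub <- feed + 36.00 + 25.00 + 7.87 * ha + 39.36 + 16.32 * ha +
    0.05 * revenue
  variable <- var_sub + 0.05 * var_sub
  overhead <- 26.04 + 28.06
  fixed <- overhead + 0.10 * overhead + 0.033 * (variable + overhead)
  net_oracle <- revenue - variable - fixed

  b <- enterprise_budget(dbw, age, 2018, steer_ww, heifer_ww, ir)
  expect_equal(b$revenue, revenue, tolerance = 1e-10)
  expect_equal(b$net_return, net_oracle, tolerance = 1e-10)
  expect_equal(b$net_return_per_ha, net_oracle / ha, tolerance = 1e-10)
})

test_that("budget components sum to their totals to the cent and the net
           return identity holds for every tier and year", {
  fs <- forage_spec()
  plan <- season_plan(200)
  tiers <- weight_tiers()
  mid <- c(420, (tiers$lower[2:10] + tiers$upper[2:10]) / 2, 650)
  for (year in c(2011, 2014, 2018)) {
    for (w in mid) {
      ir <- seasonal_intake(w, plan, fs)
      b <- enterprise_budget(w, 5, year,
                             steer_ww = predict_ww(w, 35, "steer", 5),
                             heifer_ww = predict_ww(w, 35, "heifer", 5),
                             intake = ir)
      parts <- split(b$components$value, b$components$category)
      expect_equal(sum(parts$revenue), b$revenue, tolerance = 0.005)
      expect_equal(sum(parts$variable), b$variable_cost, tolerance = 0.005)
      expect_equal(sum(parts$fixed), b$fixed_cost, tolerance = 0.005)
      expect_equal(b$revenue - (b$variable_cost + b$fixed_cost),
                   b$net_return, tolerance = 0.005)
      expect_equal(b$net_return_per_ha, b$net_return / b$ha_per_cow)
    }
  }
})

test_that("heavier cows carry weakly higher feed cost and cull-related
           revenue in the same year", {
  fs <- forage_spec(); plan <- season_plan(200)
  comp <- function(w) {
    b <- enterprise_budget(w, 11, 2018,
                           steer_ww = predict_ww(w, 35, "steer", 11),
                           heifer_ww = predict_ww(w, 35, "heifer", 11),
                           intake = seasonal_intake(w, plan, fs))
    c(feed = b$components$value[b$components$item == "feed"],
      cull = b$components$value[b$components$item == "revenue_cull_cow"])
  }
  w <- seq(440, 640, by = 50)
  m <- t(vapply(w, comp, numeric(2)))
  expect_true(all(diff(m[, "feed"]) > 0))
  expect_true(all(diff(m[, "cull"]) > 0))
})

test_that("machinery and livestock fixed cost includes cow and bull
           depreciation and varies with cow weight", {
  m_light <- machinery_livestock_cost(430.84, cull_bull_price = 1.34)
  m_heavy <- machinery_livestock_cost(634.92, cull_bull_price = 1.34)
  # heavier bulls salvage for more, so their depreciation share is smaller
  expect_lt(m_heavy, m_light)
  expect_equal(m_light - 37,
               41.735 + (3060 - (430.84 / 0.7) * 1.34) / 5 / 25)
})
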