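test_that("cow growth trajectory follows the 85% entry and 4%/yr rule to a
           mature plateau", {
  expect_equal(cow_weight_trajectory(600, 2), 510)
  expect_equal(cow_weight_trajectory(600, 4), 558)
  expect_equal(cow_weight_trajectory(600, 6), 600)
  expect_equal(cow_weight_trajectory(600, 9), 600)
  expect_equal(cow_weight_trajectory(600, 2:6) / 600,
               c(0.85, 0.89, 0.93, 0.97, 1.00))
  expect_error(cow_weight_trajectory(600, 1), "unsupported age")
  expect_error(cow_weight_trajectory(0, 3), "positive")
})

test_that("price forecasting chains year-over-year changes from the base
           year", {
  base <- list(year = 2019, hay = 100)
  ch <- data.frame(year = 2020:2021, hay = c(0.10, -0.10))
  out <- forecast_prices(base, ch, 2)
  expect_equal(out$hay, c(100, 110, 99))
  # zero changes give a flat path
  flat <- forecast_prices(base, data.frame(year = 2020:2024, hay = 0), 5)
  expect_true(all(flat$hay == 100))
  expect_error(forecast_prices(base, ch, 5), "configuration")

  # replaying the packaged projected hay changes reproduces the schedule
  proj <- cost_schedule("projected")
  ch_hay <- data.frame(year = proj$year[-1],
                       hay_ton = diff(proj$hay_ton) / head(proj$hay_ton, -1))
  replay <- forecast_prices(list(year = 2019, hay_ton = 192.51), ch_hay, 8)
  expect_equal(replay$hay_ton, proj$hay_ton, tolerance = 1e-10)
  expect_equal(replay$hay_ton[replay$year == 2021], 240.63, tolerance = 1e-10)
  expect_equal(replay$hay_ton[replay$year == 2022], 319.06, tolerance = 1e-10)
})

test_that("single-year NPV is the discounted per-ha net return", {
  cfg <- small_scenario()
  cfg$horizon <- 1
  d <- npv_for_class(500, 200, cfg, detail = TRUE)
  expect_equal(d$npv,
               d$years$net_return[1] / (1.05 * d$years$ha_per_cow[1]))
})

test_that("the NPV grid is deterministic, rectangular, and reduces to a
           single evaluation for a 1x1 grid", {
  cfg <- small_scenario()
  g1 <- sensitivity_grid(cfg)
  g2 <- sensitivity_grid(cfg)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(2, 2))
  single <- small_scenario(weights = 430.84, grazing = 200)
  expect_equal(as.numeric(sensitivity_grid(single)),
               npv_for_class(430.84, 200, single))
})

test_that("under the default configuration NPVs are negative, rise with
           grazing days, and discounting moves all-negative flows toward
           zero", {
  cfg <- small_scenario(weights = c(430.84, 538.74), grazing = c(175, 200, 225))
  g <- sensitivity_grid(cfg)
  expect_true(all(g < 0))
  expect_true(all(diff(t(g)) > 0))  # more grazing, less hay: higher NPV

  # heavy class on a short grazing season: every yearly flow is negative,
  # so a higher discount rate must shrink the discounted loss
  d <- npv_for_class(634.92, 175, cfg, detail = TRUE)
  expect_true(all(d$years$net_return < 0))
  cfg_hi <- cfg
  cfg_hi$discount_rate <- 0.10
  expect_gt(npv_for_class(634.92, 175, cfg_hi),
            npv_for_class(634.92, 175, cfg))
})

test_that("relative change grids are zero at the reference and reproduce
           hand arithmetic", {
  g <- matrix(c(-100, -50, -80, -120), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  rc <- relative_change_grid(g, ref_row = "a", ref_col = "x")
  expect_equal(rc["a", "x"], 0)
  expect_equal(rc["b", "x"], 100 * (-50 + 100) / 100)
  expect_equal(rc["a", "y"], 20)
  zero_ref <- matrix(0, 1, 1)
  expect_error(relative_change_grid(zero_ref, 1, 1), "reference")
})

test_that("the transcribed reference grids load in the report layout and the
           ranking logic picks the published optima", {
  ref <- reference_npv_grid("npv")
  expect_equal(dim(ref), c(10, 11))
  expect_equal(attr(ref, "baseline"), "200")
  expect_equal(ref["430.84", "200"], -537.44)

  opt <- optimal_class(ref)
  expect_equal(unname(opt["200"]), 453.51)
  expect_true(all(opt[c("205", "210", "215", "220", "225")] == 430.84))
  # single-row grid returns that class everywhere
  expect_true(all(optimal_class(ref[1, , drop = FALSE]) == 430.84))
})

test_that("NPV grids round-trip to the conventional CSV layout", {
  cfg <- small_scenario()
  g <- sensitivity_grid(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_npv_grid(g, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(df), c("cow_kg", "175", "Baseline"))
  expect_equal(df[["175"]], unname(round(g[, "175"], 2)))
})
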