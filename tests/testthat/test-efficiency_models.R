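test_that("packaged coefficient sets evaluate to the hand-computed linear
           predictors at herd-mean covariates", {
  cwp <- efficiency_coefficients("cwp")
  ww <- efficiency_coefficients("ww")
  yw <- efficiency_coefficients("yw")

  # hand evaluations at the herd-mean covariates (steer calf, 35 kg birth,
  # age 4.57, cow 538.74 kg)
  expect_equal(predict_cwp(538.74, 35, "steer", 4.57), 46.5, tolerance = 0.01)
  expect_equal(predict_ww(538.74, 35, "steer", 4.57), 249.8, tolerance = 0.01)
  expect_equal(predict_yw(538.74, 35, "steer", 4.57), 351.9, tolerance = 0.01)

  # term-by-term oracle agreement
  for (resp in list(cwp, ww, yw)) {
    est <- c(intercept = resp$intercept, ln_dbw = resp$b_ln_dbw,
             birth_wt = resp$b_birth, heifer = resp$b_heifer,
             steer = resp$b_steer, age = resp$b_age, age2 = resp$b_age2)
    expect_equal(predict_efficiency(480, 33, "heifer", 3, resp),
                 unname(oracle_predictor(est, 480, 33, "heifer", 3)))
  }

  # sex contrasts are coefficient differences
  expect_equal(predict_cwp(500, 35, "heifer", 4) - predict_cwp(500, 35, "steer", 4),
               -3.02)
  expect_equal(predict_yw(500, 35, "heifer", 4) - predict_yw(500, 35, "steer", 4),
               -50.23)

  # age response of YW peaks near 7.07 yr (vertex of the quadratic)
  expect_equal(-yw$b_age / (2 * yw$b_age2), 7.069, tolerance = 0.001)

  expect_error(predict_cwp(-1, 35, "steer", 4), "positive")
})

test_that("a 1% weight increase moves CWP and WW by the published
           elasticities, in opposite directions", {
  d_cwp <- predict_cwp(538.74 * 1.01, 35, "steer", 4.57) -
    predict_cwp(538.74, 35, "steer", 4.57)
  d_ww <- predict_ww(538.74 * 1.01, 35, "steer", 4.57) -
    predict_ww(538.74, 35, "steer", 4.57)
  expect_equal(d_cwp, -38.58 * log(1.01))
  expect_equal(d_ww, 36.92 * log(1.01))
  expect_lt(d_cwp, 0)
  expect_gt(d_ww, 0)
  # CWP strictly decreasing, WW strictly increasing across the tier range
  w <- seq(430, 640, by = 10)
  expect_true(all(diff(predict_cwp(w, 35, "steer", 4.57)) < 0))
  expect_true(all(diff(predict_ww(w, 35, "steer", 4.57)) > 0))
})

test_that("predictions at herd-mean covariates sit within one SD of the
           published herd means", {
  expect_lt(abs(predict_ww(538.74, 35, "steer", 4.57) - 249.35), 32.45)
  expect_lt(abs(predict_yw(538.74, 35, "steer", 4.57) - 349.83), 42.64)
})

test_that("noiseless generation is recovered exactly by the mixed-model
           refit (up to the reference-level reparameterization)", {
  p <- herd_generator_params(n_cows = 60, n_years = 4,
                             year_sd = 0, cow_sd = 0, residual_sd = 0,
                             yw_year_sd = 0, yw_cow_sd = 0, yw_residual_sd = 0)
  herd <- generate_herd(p, seed = 7)
  # the zero-variance fit sits on the parameter boundary; lme4 warns about
  # its gradient check but the fixed effects are exact
  fit <- suppressWarnings(fit_efficiency_model(herd, "ww"))
  gen <- efficiency_coefficients("ww")
  tol <- 1e-6
  expect_equal(fit$coefficients$b_ln_dbw, gen$b_ln_dbw, tolerance = tol)
  expect_equal(fit$coefficients$b_birth, gen$b_birth, tolerance = tol)
  expect_equal(fit$coefficients$b_age, gen$b_age, tolerance = tol)
  expect_equal(fit$coefficients$b_age2, gen$b_age2, tolerance = tol)
  # heifer is the fitted reference level: the intercept absorbs its offset
  # and the steer term becomes the steer-heifer contrast
  expect_equal(fit$coefficients$intercept, gen$intercept + gen$b_heifer,
               tolerance = tol)
  expect_equal(fit$coefficients$b_steer, gen$b_steer - gen$b_heifer,
               tolerance = tol)
})

test_that("the refit reports a sensible variance partition and rejects
           degenerate designs", {
  herd <- generate_herd(herd_generator_params(n_cows = 80, n_years = 4),
                        seed = 21)
  fit <- fit_efficiency_model(herd, "ww")
  expect_true(fit$marginal_r2 >= 0 && fit$marginal_r2 <= fit$conditional_r2)
  expect_true(fit$conditional_r2 <= 1)
  expect_gt(fit$coefficients$year_sd, 0)

  one_year <- herd[herd$year == herd$year[1], ]
  expect_error(fit_efficiency_model(one_year, "ww"), "year")
  one_cow <- herd[1:60, ]
  one_cow$cow_id <- "C0001"
  one_cow$year <- rep(2011:2014, length.out = 60)
  expect_error(fit_efficiency_model(one_cow, "ww"), "cow")
})

test_that("a zero quadratic age effect is covered by its interval in most
           replicates", {
  cc <- efficiency_coefficients("ww")
  cc$b_age2 <- 0
  p <- herd_generator_params(n_cows = 50, n_years = 4, coeffs = cc)
  covered <- vapply(1:20, function(s) {
    fit <- fit_efficiency_model(generate_herd(p, seed = 100 + s), "ww")
    ci <- fit$ci["I(age^2)", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 16)
})

test_that("weaned output per hectare scales as a ratio and declines with cow
           weight on intake-linked synthetic herds", {
  expect_equal(weaned_kg_per_ha(240, 0.8), 300)
  expect_equal(weaned_kg_per_ha(240, 1.6), 150)  # doubling land halves it
  expect_error(weaned_kg_per_ha(240, 0), "positive")

  herd <- generate_herd(herd_generator_params(), seed = 3)
  fs <- forage_spec()
  plan <- season_plan(200)
  herd$ha_per_cow <- vapply(herd$dbw, function(w) {
    seasonal_intake(w, plan, fs)$ha_per_cow
  }, numeric(1))
  op <- fit_output_per_ha(herd)
  expect_lt(op$slope_per_100kg, 0)
})
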