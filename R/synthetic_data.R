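#' Parameters for the synthetic herd generator
#'
#' Defaults emulate the study herd's cross-sectional moments: observed
#' BCS-5 weight 538.74 +/- 65.37 kg, BCS 5.37 +/- 0.44, ~130 cows over 8
#' years, mean cow age ~4.6 yr under a stationary open herd with 28% annual
#' replacement. Weaning weights are generated from the packaged
#' weaning-weight regression plus crossed year and cow random intercepts;
#' the noise SDs are derived from the printed variance partition (marginal
#' and conditional R^2) of the fitted models against the printed herd SDs.
#'
#' @param n_cows Herd size per year.
#' @param n_years Number of calendar years.
#' @param start_year First calendar year.
#' @param mean_dbw,sd_dbw Target observed (cross-sectional) DBW moments, kg.
#' @param bcs_mean,bcs_sd Body condition score moments.
#' @param bcs_adjustment Per-score weight fraction (see
#'   [normalize_to_bcs5()]).
#' @param replacement_rate Annual probability a cow leaves the herd and is
#'   replaced by an age-2 heifer.
#' @param max_age Oldest age kept in the herd.
#' @param growth_k Slope of the logistic growth curve in age (inflection at
#'   age 4).
#' @param birth_mean,birth_sd Calf birth weight distribution, kg (synthetic
#'   defaults; the study herd's birth-weight distribution is unreported).
#' @param sex_prob_steer Probability a calf is a steer.
#' @param response_model `"ww"`: generate weaning weight from the WW
#'   coefficient set; `"cwp"`: generate the weaning-weight ratio from the
#'   CWP set and back out WW.
#' @param coeffs Coefficient set used for generation (defaults to the
#'   packaged set for `response_model`).
#' @param year_sd,cow_sd,residual_sd Random-effect and residual SDs on the
#'   response scale (kg for WW, percent for CWP).
#' @param yw_coeffs,yw_year_sd,yw_cow_sd,yw_residual_sd Same for yearling
#'   weight.
#' @param missing_yw_rate Fraction of yearling weights set missing
#'   completely at random (~16% in the study herd); default 0.
#' @return A list of class `herd_generator_params`.
#' @export
herd_generator_params <- function(n_cows = 130, n_years = 8,
                                  start_year = 2011,
                                  mean_dbw = 538.74, sd_dbw = 65.37,
                                  bcs_mean = 5.37, bcs_sd = 0.44,
                                  bcs_adjustment = 0.04,
                                  replacement_rate = 0.28, max_age = 14,
                                  growth_k = 1.5,
                                  birth_mean = 35, birth_sd = 4,
                                  sex_prob_steer = 0.5,
                                  response_model = c("ww", "cwp"),
                                  coeffs = NULL,
                                  year_sd = NULL, cow_sd = NULL,
                                  residual_sd = NULL,
                                  yw_coeffs = efficiency_coefficients("yw"),
                                  yw_year_sd = 11, yw_cow_sd = 11,
                                  yw_residual_sd = 35,
                                  missing_yw_rate = 0) {
  response_model <- match.arg(response_model)
  if (is.null(coeffs)) coeffs <- efficiency_coefficients(response_model)
  # noise defaults by response scale (kg for WW, percent points for CWP)
  if (is.null(year_sd)) year_sd <- if (response_model == "ww") 13 else 3.5
  if (is.null(cow_sd)) cow_sd <- if (response_model == "ww") 13 else 3.5
  if (is.null(residual_sd)) residual_sd <- if (response_model == "ww") 23 else 4
  p <- list(n_cows = n_cows, n_years = n_years, start_year = start_year,
            mean_dbw = mean_dbw, sd_dbw = sd_dbw,
            bcs_mean = bcs_mean, bcs_sd = bcs_sd,
            bcs_adjustment = bcs_adjustment,
            replacement_rate = replacement_rate, max_age = max_age,
            growth_k = growth_k,
            birth_mean = birth_mean, birth_sd = birth_sd,
            sex_prob_steer = sex_prob_steer,
            response_model = response_model, coeffs = coeffs,
            year_sd = year_sd, cow_sd = cow_sd, residual_sd = residual_sd,
            yw_coeffs = yw_coeffs, yw_year_sd = yw_year_sd,
            yw_cow_sd = yw_cow_sd, yw_residual_sd = yw_residual_sd,
            missing_yw_rate = missing_yw_rate)
  stopifnot(p$n_cows >= 1, p$n_years >= 1, sd_dbw >= 0, bcs_sd >= 0,
            year_sd >= 0, cow_sd >= 0, residual_sd >= 0,
            sex_prob_steer >= 0, sex_prob_steer <= 1,
            replacement_rate >= 0, replacement_rate < 1)
  structure(p, class = "herd_generator_params")
}

# fraction of mature weight at a given age: logistic with inflection at 4 yr
# rising from 85% (the age-2 entry weight) to the mature asymptote
growth_fraction <- function(age, k = 1.5) {
  0.85 + 0.15 / (1 + exp(-k * (age - 4)))
}

#' Generate a synthetic herd of cow-year records
#'
#' Simulates an open, stationary herd: cows carry a persistent mature
#' weight and random intercept, age one year per calendar year, leave with
#' a fixed annual replacement probability (or at `max_age`) and are
#' replaced by age-2 heifers. Body weight follows a logistic growth curve
#' to the cow's mature weight. Because young cows sit below their mature
#' weight, the latent mature-weight distribution is calibrated against the
#' stationary age distribution so that the *observed* cross-section matches
#' the target DBW moments. Weaning (and yearling) weights are the
#' coefficient-set linear predictor plus crossed year and cow random
#' intercepts and a residual.
#'
#' @param params A [herd_generator_params()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return data.frame of cow-year records in the herd CSV layout
#'   (`cow_id`, `year`, `age`, `bw`, `bcs`, `dbw`, `calf_sex`,
#'   `calf_birth_wt`, `ww205`, `yw`).
#' @export
#' @examples
#' herd <- generate_herd(herd_generator_params(n_cows = 20, n_years = 3),
#'                       seed = 1)
#' summarize_herd(herd)
generate_herd <- function(params = herd_generator_params(), seed = 1) {
  if (!inherits(params, "herd_generator_params")) {
    stop("configuration error: params must come from herd_generator_params()",
         call. = FALSE)
  }
  p <- params
  set.seed(seed)

  # stationary age distribution of the open herd: geometric survival from
  # age 2, truncated at max_age
  ages <- 2:p$max_age
  age_probs <- (1 - p$replacement_rate)^(ages - 2)
  age_probs <- age_probs / sum(age_probs)
  frac <- growth_fraction(ages, p$growth_k)
  e_frac <- sum(age_probs * frac)
  e_frac2 <- sum(age_probs * frac^2)
  v_frac <- e_frac2 - e_frac^2
  # calibrate the latent mature-weight distribution so the observed
  # cross-section (mature weight x growth fraction) hits the target moments
  mu_mature <- p$mean_dbw / e_frac
  var_mature <- (p$sd_dbw^2 - v_frac * mu_mature^2) / e_frac2
  if (var_mature <= 0) {
    stop("configuration error: sd_dbw too small for the growth-curve spread",
         call. = FALSE)
  }
  sd_mature <- sqrt(var_mature)

  new_cow <- function(n, next_id) {
    list(id = sprintf("C%04d", next_id + seq_len(n) - 1),
         mature = stats::rnorm(n, mu_mature, sd_mature),
         cow_eff = stats::rnorm(n, 0, p$cow_sd),
         cow_eff_yw = stats::rnorm(n, 0, p$yw_cow_sd))
  }

  herd <- new_cow(p$n_cows, 1)
  herd$age <- sample(ages, p$n_cows, replace = TRUE, prob = age_probs)
  next_id <- p$n_cows + 1
  year_eff <- stats::rnorm(p$n_years, 0, p$year_sd)
  year_eff_yw <- stats::rnorm(p$n_years, 0, p$yw_year_sd)

  out <- vector("list", p$n_years)
  for (y in seq_len(p$n_years)) {
    if (y > 1) {
      herd$age <- herd$age + 1
      leave <- herd$age > p$max_age |
        stats::runif(p$n_cows) < p$replacement_rate
      if (any(leave)) {
        repl <- new_cow(sum(leave), next_id)
        next_id <- next_id + sum(leave)
        herd$id[leave] <- repl$id
        herd$mature[leave] <- repl$mature
        herd$cow_eff[leave] <- repl$cow_eff
        herd$cow_eff_yw[leave] <- repl$cow_eff_yw
        herd$age[leave] <- 2
      }
    }
    dbw <- herd$mature * growth_fraction(herd$age, p$growth_k)
    bcs <- pmin(9, pmax(1, stats::rnorm(p$n_cows, p$bcs_mean, p$bcs_sd)))
    bw <- dbw / (1 + p$bcs_adjustment * (5 - bcs))
    sex <- ifelse(stats::runif(p$n_cows) < p$sex_prob_steer,
                  "steer", "heifer")
    birth <- stats::rnorm(p$n_cows, p$birth_mean, p$birth_sd)
    pred <- predict_efficiency(dbw, birth, sex, herd$age, p$coeffs)
    resp <- pred + year_eff[y] + herd$cow_eff +
      stats::rnorm(p$n_cows, 0, p$residual_sd)
    ww205 <- if (p$response_model == "cwp") resp * dbw / 100 else resp
    yw <- predict_efficiency(dbw, birth, sex, herd$age, p$yw_coeffs) +
      year_eff_yw[y] + herd$cow_eff_yw +
      stats::rnorm(p$n_cows, 0, p$yw_residual_sd)
    if (p$missing_yw_rate > 0) {
      yw[stats::runif(p$n_cows) < p$missing_yw_rate] <- NA_real_
    }
    out[[y]] <- data.frame(
      cow_id = herd$id, year = p$start_year + y - 1, age = herd$age,
      bw = bw, bcs = bcs, dbw = dbw, calf_sex = sex,
      calf_birth_wt = birth, ww205 = ww205, yw = yw,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Write a synthetic herd in the herd-reader CSV dialect
#'
#' @param herd data.frame from [generate_herd()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_herd_csv <- function(herd, path) {
  cols <- c("cow_id", "year", "age", "bw", "bcs", "calf_sex",
            "calf_birth_wt", "ww205", "yw")
  utils::write.csv(herd[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Generate price paths under a simple change model
#'
#' Stands in for unpublished market forecast series. `"replay"` chains a
#' supplied series of year-over-year fractional changes (deterministic),
#' `"constant"` holds prices flat, `"white_noise"` applies independent
#' Gaussian fractional shocks of a given SD (seeded).
#'
#' @param base Named list of base-year values including `year`.
#' @param model `"replay"`, `"constant"` or `"white_noise"`.
#' @param horizon Forecast years beyond the base year.
#' @param changes data.frame of fractional changes (for `"replay"`).
#' @param sd Shock standard deviation (for `"white_noise"`).
#' @param seed Seed for the noise model.
#' @return data.frame of class `price_series`.
#' @export
generate_price_paths <- function(base, model = c("replay", "constant",
                                                 "white_noise"),
                                 horizon = 10, changes = NULL, sd = 0,
                                 seed = 1) {
  model <- match.arg(model)
  base <- as.list(base)
  cols <- setdiff(names(base), "year")
  if (model == "replay") {
    if (is.null(changes)) {
      stop("configuration error: replay model needs a change series",
           call. = FALSE)
    }
    return(forecast_prices(base, changes, horizon))
  }
  years <- base$year + 1:horizon
  if (model == "constant" || sd == 0) {
    deltas <- matrix(0, horizon, length(cols),
                     dimnames = list(NULL, cols))
  } else {
    set.seed(seed)
    deltas <- matrix(stats::rnorm(horizon * length(cols), 0, sd),
                     horizon, length(cols), dimnames = list(NULL, cols))
  }
  changes <- data.frame(year = years, deltas, check.names = FALSE)
  forecast_prices(base, changes, horizon)
}
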