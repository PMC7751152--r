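#' Cow weight along the growth trajectory
#'
#' A replacement female reaches 85% of her mature weight by age 2 and gains
#' 4% of mature weight per year until plateauing at maturity (age 6).
#'
#' @param mature_wt Mature body weight, kg (> 0). Pass 1 to get the bare
#'   fraction of mature weight.
#' @param age Cow age, yr (>= 2; pre-first-calving heifers are outside the
#'   herd model).
#' @return Body weight at `age`, kg.
#' @export
#' @examples
#' cow_weight_trajectory(600, 2:7)
cow_weight_trajectory <- function(mature_wt, age) {
  if (any(mature_wt <= 0)) stop("mature_wt must be positive", call. = FALSE)
  if (any(age < 2)) {
    stop("unsupported age: growth rule starts at age 2", call. = FALSE)
  }
  frac <- pmin(1, 0.85 + 0.04 * (age - 2))
  mature_wt * frac
}

#' Load a scenario configuration
#'
#' @param path YAML scenario file; default the packaged baseline (10 mature
#'   weight classes, 175--225 grazing days, 10-yr horizon, 5% discount,
#'   40.5 ha).
#' @return A list of class `scenario_config`.
#' @export
load_scenario_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenario_baseline.yaml",
                        package = "cowsize", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(cfg$horizon >= 1, cfg$discount_rate >= 0,
            length(cfg$mature_weights) >= 1,
            length(cfg$grazing_days_grid) >= 1)
  structure(cfg, class = "scenario_config")
}

#' Forecast a price path by replaying year-over-year changes
#'
#' `P(t+1) = P(t) * (1 + delta(t))`, anchored at actual base-year prices.
#'
#' @param base Named list or one-row data.frame of base-year prices,
#'   including `year`.
#' @param changes data.frame with `year` and one fractional-change column
#'   per price column to be forecast.
#' @param horizon Number of forecast years beyond the base year.
#' @return data.frame of class `price_series`, base year first.
#' @export
#' @examples
#' forecast_prices(list(year = 2019, hay = 100),
#'                 data.frame(year = 2020:2021, hay = c(0.10, -0.10)), 2)
forecast_prices <- function(base, changes, horizon = nrow(changes)) {
  base <- as.list(base)
  years <- base$year + seq_len(horizon)
  missing_years <- setdiff(years, changes$year)
  if (length(missing_years)) {
    stop("configuration error: no price change for year ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  cols <- setdiff(intersect(names(base), names(changes)), "year")
  out <- data.frame(year = c(base$year, years))
  for (col in cols) {
    path <- numeric(horizon + 1)
    path[1] <- base[[col]]
    for (i in seq_len(horizon)) {
      delta <- changes[[col]][changes$year == years[i]]
      path[i + 1] <- path[i] * (1 + delta)
    }
    out[[col]] <- path
  }
  class(out) <- c("price_series", class(out))
  out
}

#' Forward price series for the NPV horizon
#'
#' Packaged base-year prices extended over the horizon by replaying the
#' packaged (synthetic) cattle-cycle change series.
#'
#' @param start_year First forecast-anchored year (actual prices).
#' @param horizon Total years covered, counting the base year as year 1.
#' @param prices,changes Optional user-supplied series (same layouts as the
#'   packaged CSVs).
#' @return A `price_series` covering `start_year .. start_year + horizon - 1`.
#' @export
npv_price_series <- function(start_year = 2019, horizon = 10,
                             prices = price_series(), changes = NULL) {
  if (is.null(changes)) {
    changes <- utils::read.csv(
      system.file("extdata", "price_changes_synthetic.csv",
                  package = "cowsize", mustWork = TRUE))
  }
  forecast_prices(price_year(prices, start_year), changes, horizon - 1)
}

#' Net present value of one mature-weight class
#'
#' Simulates one cow of the given mature weight entering the herd at age 2
#' and aging one year per period over the horizon. Each year her weight
#' follows [cow_weight_trajectory()], intake and stocking follow the season
#' plan for the scenario's grazing days, expected calf weaning weights come
#' from the weaning-weight regression at her current weight and age, and the
#' enterprise budget produces the expected net return. Yearly net returns
#' are discounted and expressed per hectare:
#' `NPV = sum_t net_return_t / ((1 + r)^t * ha_per_cow_t)`.
#'
#' @param mature_wt Mature cow weight, kg.
#' @param grazing_days Grazing season length for the scenario, d.
#' @param config A [load_scenario_config()].
#' @param costs Projected [cost_schedule()].
#' @param prices A `price_series` covering the horizon (see
#'   [npv_price_series()]).
#' @param culls A [cull_schedule()].
#' @param ww_coeffs Weaning-weight coefficient set.
#' @param detail If `TRUE`, also return the per-year budget table.
#' @return NPV in $ per ha (discounted sum), or a list with `npv` and
#'   `years` when `detail = TRUE`.
#' @export
npv_for_class <- function(mature_wt, grazing_days,
                          config = load_scenario_config(),
                          costs = cost_schedule("projected"),
                          prices = npv_price_series(config$start_year,
                                                    config$horizon),
                          culls = cull_schedule(),
                          ww_coeffs = efficiency_coefficients("ww"),
                          detail = FALSE) {
  forage <- do.call(forage_spec, config$forage)
  plan <- do.call(season_plan, c(list(grazing_days = grazing_days),
                                 config$season))
  r <- config$discount_rate
  npv <- 0
  rows <- vector("list", config$horizon)
  for (t in seq_len(config$horizon)) {
    age <- config$entry_age + t - 1
    w <- cow_weight_trajectory(mature_wt, age)
    milk <- config$peak_milk * cow_weight_trajectory(1, age)
    intake <- seasonal_intake(w, plan, forage, milk_yield = milk)
    herd_n <- herd_size(config$total_land, intake$ha_per_cow)
    budget <- enterprise_budget(
      dbw = w, age = age, year = config$start_year + t - 1,
      steer_ww = predict_efficiency(w, config$birth_wt, "steer", age, ww_coeffs),
      heifer_ww = predict_efficiency(w, config$birth_wt, "heifer", age, ww_coeffs),
      intake = intake, prices = prices, costs = costs, culls = culls,
      herd_n = herd_n
    )
    npv <- npv + budget$net_return / ((1 + r)^t * intake$ha_per_cow)
    if (detail) {
      rows[[t]] <- data.frame(t = t, year = budget$year, age = age,
                              cow_wt = w, ha_per_cow = intake$ha_per_cow,
                              revenue = budget$revenue,
                              variable_cost = budget$variable_cost,
                              fixed_cost = budget$fixed_cost,
                              net_return = budget$net_return)
    }
  }
  if (detail) list(npv = npv, years = do.call(rbind, rows)) else npv
}

#' NPV sensitivity grid over weight classes and grazing days
#'
#' One [npv_for_class()] evaluation per (mature weight, grazing days) cell.
#' Hay days are `364 - grazing days` with the cold-stress segment fixed, so
#' shorter grazing seasons feed more hay (partly at lactating intake).
#' Deterministic given the configuration and price tables.
#'
#' @inheritParams npv_for_class
#' @return A numeric matrix of class `npv_grid` (weight rows, grazing-day
#'   columns) with a `baseline` attribute naming the baseline column.
#' @export
sensitivity_grid <- function(config = load_scenario_config(),
                             costs = cost_schedule("projected"),
                             prices = npv_price_series(config$start_year,
                                                       config$horizon),
                             culls = cull_schedule(),
                             ww_coeffs = efficiency_coefficients("ww")) {
  wts <- config$mature_weights
  gds <- config$grazing_days_grid
  grid <- matrix(NA_real_, length(wts), length(gds),
                 dimnames = list(format(wts, nsmall = 2), as.character(gds)))
  for (i in seq_along(wts)) {
    for (j in seq_along(gds)) {
      grid[i, j] <- npv_for_class(wts[i], gds[j], config, costs, prices,
                                  culls, ww_coeffs)
    }
  }
  attr(grid, "baseline") <- as.character(config$baseline_grazing_days)
  class(grid) <- c("npv_grid", class(grid))
  grid
}

#' Relative change of an NPV grid against a reference cell
#'
#' `100 * (NPV_cell - NPV_ref) / |NPV_ref|`; a positive number reflects a
#' positive change in net present value relative to the reference. The
#' reference cell maps to 0.
#'
#' @param grid Numeric NPV matrix (weight rows, grazing-day columns).
#' @param ref_row,ref_col Row/column of the reference cell (name or index);
#'   defaults: first row (lightest class) and the grid's baseline column.
#' @return Matrix of percent changes, same shape as `grid`.
#' @export
relative_change_grid <- function(grid, ref_row = 1,
                                 ref_col = attr(grid, "baseline") %||% 1) {
  ref <- grid[ref_row, ref_col]
  if (!is.finite(ref) || ref == 0) {
    stop("undefined reference: reference NPV must be finite and nonzero",
         call. = FALSE)
  }
  out <- 100 * (grid - ref) / abs(ref)
  attr(out, "baseline") <- attr(grid, "baseline")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weight class with maximum NPV per scenario
#'
#' @param grid Numeric NPV matrix with weight-class row names.
#' @return Named numeric vector: for each grazing-day column, the mature
#'   weight (kg) with the highest NPV. Ties break toward the lighter class.
#' @export
optimal_class <- function(grid) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  # rows are ordered light to heavy, so which.max's first-hit rule breaks
  # ties toward the lighter class
  idx <- apply(grid, 2, which.max)
  stats::setNames(as.numeric(rownames(grid))[idx], colnames(grid))
}

#' Transcribed reference NPV grids
#'
#' The NPV (in $) and relative-change (in %) grids reported for the study
#' herd, transcribed at their printed precision (cents / two decimals).
#' These are validation fixtures: absolute NPVs depend on unpublished
#' market price forecasts, so the package checks its relative-change
#' arithmetic and ranking logic against them rather than regenerating them.
#'
#' @param which `"npv"` ($ grid) or `"relchange"` (% grid).
#' @return Numeric matrix of class `npv_grid`; columns named by grazing
#'   days with the 200-d baseline column flagged in the `baseline`
#'   attribute.
#' @export
reference_npv_grid <- function(which = c("npv", "relchange")) {
  which <- match.arg(which)
  file <- switch(which, npv = "npv_reference_grid.csv",
                 relchange = "npv_reference_relchange.csv")
  df <- utils::read.csv(system.file("extdata", file, package = "cowsize",
                                    mustWork = TRUE), check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- format(df$cow_kg, nsmall = 2)
  colnames(m)[colnames(m) == "baseline"] <- "200"
  attr(m, "baseline") <- "200"
  class(m) <- c("npv_grid", class(m))
  m
}

#' Write an NPV grid as CSV in the conventional report layout
#'
#' @param grid An `npv_grid` matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_npv_grid <- function(grid, path) {
  cols <- colnames(grid)
  base <- attr(grid, "baseline")
  if (!is.null(base)) cols[cols == base] <- "Baseline"
  df <- data.frame(cow_kg = rownames(grid), round(unclass(grid), 2),
                   check.names = FALSE)
  names(df) <- c("cow_kg", cols)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
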