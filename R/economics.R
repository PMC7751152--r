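#' Load a cost schedule
#'
#' Per-year enterprise cost assumptions. The package ships two schedules:
#' the historical 2011--2018 table (labor and pasture care on a per-cow
#' basis, taxes 3.3% of expenditures) and the projected 2019--2027 table
#' (labor as an hourly wage for 500 h spread over the herd, pasture care per
#' hectare, taxes 2.8%). Users may supply their own CSV in the same layout;
#' `inst/extdata/cost_row_labels.csv` maps column names to the conventional
#' budget row labels.
#'
#' @param which `"historical"` or `"projected"`; ignored when `path` given.
#' @param path Optional path to a user-supplied schedule CSV.
#' @return data.frame keyed by `year`, of class `cost_schedule`.
#' @export
cost_schedule <- function(which = c("historical", "projected"), path = NULL) {
  which <- match.arg(which)
  if (is.null(path)) {
    path <- system.file("extdata", paste0("costs_", which, ".csv"),
                        package = "cowsize", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cost_schedule", class(df))
  df
}

#' Costs for one year, extending the projection rules when needed
#'
#' Years beyond the last row of a projected schedule are extended by the
#' schedule's own construction rules: 1% annual inflation on mineral,
#' veterinary, equipment-repair and other variable costs; labor wage grown
#' at the series' mean rate; land, pasture care and all rates held static;
#' hay carried at its last value.
#'
#' @param schedule A [cost_schedule()].
#' @param year Calendar year.
#' @return A one-row list of cost items for that year.
#' @export
cost_year <- function(schedule, year) {
  if (year %in% schedule$year) {
    return(as.list(schedule[schedule$year == year, ]))
  }
  last <- max(schedule$year)
  if (year < min(schedule$year) || is.na(last)) {
    stop("configuration error: no cost schedule for year ", year,
         call. = FALSE)
  }
  k <- year - last
  row <- as.list(schedule[schedule$year == last, ])
  infl <- 1.01^k
  for (item in c("mineral_cow", "vet_cow", "equip_repair_ha", "other_var_ha")) {
    row[[item]] <- row[[item]] * infl
  }
  if (!is.na(row$labor_wage_hr) && nrow(schedule) > 1) {
    g <- mean(diff(schedule$labor_wage_hr) / utils::head(schedule$labor_wage_hr, -1))
    row$labor_wage_hr <- row$labor_wage_hr * (1 + g)^k
  }
  row$year <- year
  row
}

#' Load a price series
#'
#' Per-year livestock sale prices in $/kg live weight. The packaged default
#' is a synthetic series (see `inst/extdata/README_synthetic_prices.txt`);
#' substitute observed market data via `path` for real analyses.
#'
#' @param path Optional path to a user-supplied CSV with columns `year`,
#'   `steer_price`, `heifer_price`, `cull_cow_price`, `cull_bull_price`.
#' @return data.frame keyed by `year`, of class `price_series`.
#' @export
price_series <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "prices_synthetic.csv",
                        package = "cowsize", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("price_series", class(df))
  df
}

#' Prices for one year
#' @param prices A [price_series()].
#' @param year Calendar year.
#' @return One-row list of prices.
#' @export
price_year <- function(prices, year) {
  if (!year %in% prices$year) {
    stop("lookup error: no prices for year ", year, call. = FALSE)
  }
  as.list(prices[prices$year == year, ])
}

#' Culling and replacement schedule
#'
#' Heifer calf revenue is discounted by the on-farm heifer retention rate;
#' cull cow revenue is weighted by the probability the cow is culled at her
#' age; cull bull revenue is shared across the cows one bull services over
#' his service life (`1 / (cows_per_bull * service_years)`).
#'
#' The default culling rule is a deterministic productive life: a cow
#' entering the herd at age 2 is culled with certainty at `cull_age` and
#' faces only the `involuntary_rate` before that.
#'
#' @param retention_rate Fraction of heifer calves retained as replacements.
#' @param cows_per_bull Cows serviced per bull per year.
#' @param service_years Bull service period, yr.
#' @param cull_age Age at certain culling, yr.
#' @param involuntary_rate Annual cull probability before `cull_age`.
#' @return A list of class `cull_schedule` with `prob_cull(age)`,
#'   `retention_rate` and `bull_share`.
#' @export
#' @examples
#' cs <- cull_schedule()
#' 1 - cs$retention_rate  # heifer revenue multiplier
#' cs$bull_share          # 1/125
cull_schedule <- function(retention_rate = 0.3207, cows_per_bull = 25,
                          service_years = 5, cull_age = 11,
                          involuntary_rate = 0) {
  stopifnot(retention_rate >= 0, retention_rate <= 1,
            involuntary_rate >= 0, involuntary_rate <= 1)
  structure(list(
    retention_rate = retention_rate,
    bull_share = 1 / (cows_per_bull * service_years),
    cull_age = cull_age,
    involuntary_rate = involuntary_rate,
    prob_cull = function(age) ifelse(age >= cull_age, 1, involuntary_rate)
  ), class = "cull_schedule")
}

#' Straight-line depreciation
#'
#' @param purchase Purchase price, $.
#' @param salvage Salvage value, $ (must not exceed purchase).
#' @param life Useful life, yr (> 0).
#' @return Annual depreciation, $/yr.
#' @export
#' @examples
#' straight_line_depreciation(1200, 782.65, 10)
straight_line_depreciation <- function(purchase, salvage, life) {
  if (any(life <= 0)) stop("life must be positive", call. = FALSE)
  if (any(salvage > purchase)) {
    stop("appreciation error: salvage exceeds purchase price", call. = FALSE)
  }
  if (any(salvage < 0)) stop("salvage must be non-negative", call. = FALSE)
  (purchase - salvage) / life
}

#' Machinery and livestock fixed cost per cow
#'
#' Livestock depreciation is computed from the stated purchase and salvage
#' conventions: cows bought at $1,200 with a $782.65 salvage after 10 yr;
#' bulls bought at $3,060, weighing cow weight / 0.70, salvaged at the cull
#' bull price after a 5-yr service period shared across 25 cows. Machinery
#' depreciation on the equipment set is a per-cow scalar (default $37/cow).
#'
#' @param cow_wt Mature cow weight, kg (drives bull salvage weight).
#' @param cull_bull_price Cull bull price, $/kg.
#' @param machinery_per_cow Machinery depreciation spread per cow, $/cow.
#' @param cow_purchase,cow_salvage,cow_life Cow depreciation convention.
#' @param bull_purchase,bull_to_cow_ratio,cows_per_bull,service_years Bull
#'   depreciation convention.
#' @return $/cow/yr fixed machinery + livestock cost.
#' @export
machinery_livestock_cost <- function(cow_wt, cull_bull_price,
                                     machinery_per_cow = 37,
                                     cow_purchase = 1200, cow_salvage = 782.65,
                                     cow_life = 10,
                                     bull_purchase = 3060,
                                     bull_to_cow_ratio = 0.70,
                                     cows_per_bull = 25, service_years = 5) {
  bull_wt <- cow_wt / bull_to_cow_ratio
  bull_salvage <- pmin(bull_wt * cull_bull_price, bull_purchase)
  cow_dep <- straight_line_depreciation(cow_purchase, cow_salvage, cow_life)
  bull_dep <- straight_line_depreciation(bull_purchase, bull_salvage,
                                         service_years) / cows_per_bull
  machinery_per_cow + cow_dep + bull_dep
}

#' Expected annual revenue per cow
#'
#' Three revenue sources: weaned calf sales (steer calves at the steer
#' price; heifer calves discounted by the retention rate), cull cow salvage
#' weighted by the age-specific cull probability, and a per-cow share of
#' cull bull salvage. The calf sex mix defaults to 0.5/0.5.
#'
#' @param steer_ww,heifer_ww Expected 205-d weaning weight by calf sex, kg.
#' @param cow_wt Cow body weight (cull sale weight), kg.
#' @param age Cow age, yr.
#' @param prices One-year price list from [price_year()].
#' @param culls A [cull_schedule()].
#' @param sex_mix Named fractions `c(steer = , heifer = )` summing to 1.
#' @param bull_to_cow_ratio Bull weight = cow weight / ratio.
#' @param literal_heifer_cull If `TRUE`, additionally weights the heifer
#'   calf term by the cull probability (the literal printed form of the
#'   revenue identity); default `FALSE` treats that as a typesetting
#'   artifact and applies the cull probability to cull cow revenue only.
#' @return A list with itemized components and `total` ($/cow).
#' @export
expected_revenue <- function(steer_ww, heifer_ww, cow_wt, age, prices, culls,
                             sex_mix = c(steer = 0.5, heifer = 0.5),
                             bull_to_cow_ratio = 0.70,
                             literal_heifer_cull = FALSE) {
  p_cull <- culls$prob_cull(age)
  heifer_mult <- 1 - culls$retention_rate
  steer_rev <- sex_mix[["steer"]] * steer_ww * prices$steer_price
  heifer_rev <- sex_mix[["heifer"]] * heifer_ww * prices$heifer_price *
    heifer_mult * (if (literal_heifer_cull) p_cull else 1)
  cull_cow_rev <- cow_wt * prices$cull_cow_price * p_cull
  cull_bull_rev <- (cow_wt / bull_to_cow_ratio) * prices$cull_bull_price *
    culls$bull_share
  list(steer = steer_rev, heifer = heifer_rev,
       cull_cow = cull_cow_rev, cull_bull = cull_bull_rev,
       total = steer_rev + heifer_rev + cull_cow_rev + cull_bull_rev)
}

#' Feed cost per cow
#'
#' Land charge on the cow's grazing footprint plus purchased/fed hay.
#'
#' @param ha_per_cow Stocking rate, ha/cow.
#' @param land_rent Land cost, $/ha.
#' @param hay_dm Annual hay fed, kg DM/cow.
#' @param hay_price_ton Hay price, $/ton.
#' @param ton_kg Kilograms per "ton" in the hay price quote; default the US
#'   short ton (907.185 kg). Set 1000 for metric tonnes.
#' @return $/cow.
#' @export
feed_cost <- function(ha_per_cow, land_rent, hay_dm, hay_price_ton,
                      ton_kg = 907.185) {
  stopifnot(ha_per_cow >= 0, land_rent >= 0, hay_dm >= 0, hay_price_ton >= 0)
  land_rent * ha_per_cow + hay_dm * hay_price_ton / ton_kg
}

#' Itemized cow-calf enterprise budget for one cow-year
#'
#' Assembles expected revenue, variable costs and fixed costs into a net
#' return per cow and per hectare. Rate-based items follow a fixed ordering
#' contract: marketing is a fraction of revenue and is itself a variable
#' cost; interest on operating capital applies to the variable-cost subtotal
#' including marketing; miscellaneous cost is a fraction of the overhead
#' (fixed) subtotal; taxes apply to all expenditures before taxes and
#' miscellaneous.
#'
#' @param dbw Cow body weight (BCS-5 normalized), kg.
#' @param age Cow age, yr.
#' @param year Budget year (looked up in `prices` and `costs`).
#' @param steer_ww,heifer_ww Expected weaning weights by calf sex, kg.
#' @param intake An `intake_result` from [seasonal_intake()].
#' @param prices A [price_series()].
#' @param costs A [cost_schedule()].
#' @param culls A [cull_schedule()].
#' @param herd_n Herd size, used to spread 500 h of labor when the schedule
#'   quotes an hourly wage; ignored for per-cow labor schedules.
#' @param labor_hours Total annual labor requirement, h.
#' @param machinery_per_cow Machinery depreciation per cow for schedules
#'   that do not list a combined machinery/livestock figure.
#' @param sex_mix,literal_heifer_cull Passed to [expected_revenue()].
#' @param ton_kg Passed to [feed_cost()].
#' @return A list of class `budget_result`: `revenue`, `variable_cost`,
#'   `fixed_cost`, `net_return` ($/cow), `net_return_per_ha`, `ha_per_cow`
#'   and an itemized `components` data.frame.
#' @export
enterprise_budget <- function(dbw, age, year, steer_ww, heifer_ww, intake,
                              prices = price_series(),
                              costs = cost_schedule("historical"),
                              culls = cull_schedule(),
                              herd_n = NULL, labor_hours = 500,
                              machinery_per_cow = 37,
                              sex_mix = c(steer = 0.5, heifer = 0.5),
                              literal_heifer_cull = FALSE,
                              ton_kg = 907.185) {
  cy <- cost_year(costs, year)
  py <- price_year(prices, year)
  ha <- intake$ha_per_cow

  rev <- expected_revenue(steer_ww, heifer_ww, dbw, age, py, culls,
                          sex_mix = sex_mix,
                          literal_heifer_cull = literal_heifer_cull)

  feed <- feed_cost(ha, cy$feed_land_ha, intake$hay_dm, cy$hay_ton,
                    ton_kg = ton_kg)
  labor <- if (!is.na(cy$labor_cow)) {
    cy$labor_cow
  } else {
    if (is.null(herd_n)) {
      stop("configuration error: hourly-wage labor needs herd_n", call. = FALSE)
    }
    cy$labor_wage_hr * labor_hours / herd_n
  }
  marketing <- cy$marketing_rate * rev$total
  var_items <- c(
    feed = feed,
    mineral = cy$mineral_cow,
    veterinary = cy$vet_cow,
    equipment_repairs = cy$equip_repair_ha * ha,
    labor = labor,
    other_variable = cy$other_var_ha * ha,
    marketing = marketing
  )
  interest <- cy$interest_rate * sum(var_items)
  variable_cost <- sum(var_items) + interest

  pasture <- if (!is.na(cy$pasture_care_cow)) cy$pasture_care_cow
             else cy$pasture_care_ha * ha
  mach <- if (!is.na(cy$machinery_livestock_cow)) {
    cy$machinery_livestock_cow
  } else {
    machinery_livestock_cost(dbw, py$cull_bull_price,
                             machinery_per_cow = machinery_per_cow)
  }
  overhead <- c(pasture_care = pasture, machinery_livestock = mach)
  misc <- cy$misc_rate * sum(overhead)
  taxes <- cy$tax_rate * (variable_cost + sum(overhead))
  fixed_cost <- sum(overhead) + misc + taxes

  net <- rev$total - (variable_cost + fixed_cost)
  components <- data.frame(
    item = c("revenue_steer", "revenue_heifer", "revenue_cull_cow",
             "revenue_cull_bull", names(var_items), "interest",
             names(overhead), "miscellaneous", "taxes"),
    category = c(rep("revenue", 4), rep("variable", length(var_items) + 1),
                 rep("fixed", length(overhead) + 2)),
    value = c(rev$steer, rev$heifer, rev$cull_cow, rev$cull_bull,
              unname(var_items), interest, unname(overhead), misc, taxes)
  )
  structure(list(
    year = year, dbw = dbw, age = age,
    revenue = rev$total,
    variable_cost = variable_cost,
    fixed_cost = fixed_cost,
    net_return = net,
    ha_per_cow = ha,
    net_return_per_ha = net / ha,
    components = components
  ), class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat(sprintf("Enterprise budget, %d: %.0f kg cow, age %.0f\n",
              x$year, x$dbw, x$age))
  cat(sprintf("  revenue  %8.2f $/cow\n", x$revenue))
  cat(sprintf("  variable %8.2f $/cow\n", x$variable_cost))
  cat(sprintf("  fixed    %8.2f $/cow\n", x$fixed_cost))
  cat(sprintf("  net      %8.2f $/cow  (%.2f $/ha at %.3f ha/cow)\n",
              x$net_return, x$net_return_per_ha, x$ha_per_cow))
  invisible(x)
}
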