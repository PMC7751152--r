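#' Forage specification
#'
#' Energy densities and annual productivity of the forage base.
#'
#' @param nem_pasture Net energy for maintenance of pasture, Mcal/kg DM.
#' @param nem_hay Net energy for maintenance of fed hay, Mcal/kg DM.
#' @param productivity Annual forage production, kg DM/ha/yr.
#' @param utilization Fraction of standing forage actually consumed, (0, 1].
#' @return A list of class `forage_spec`.
#' @export
forage_spec <- function(nem_pasture = 1.43, nem_hay = 1.20,
                        productivity = 5662, utilization = 0.5) {
  stopifnot(nem_pasture > 0, nem_hay > 0, productivity > 0,
            utilization > 0, utilization <= 1)
  structure(list(nem_pasture = nem_pasture, nem_hay = nem_hay,
                 productivity = productivity, utilization = utilization),
            class = "forage_spec")
}

#' Season plan: grazing / hay day structure of the production year
#'
#' The production year is 364 days split between grazing and hay feeding.
#' Cold-stress hay days are fixed (winter severity does not move with the
#' grazing season); the remaining hay days trade off against grazing days.
#' Hay days beyond the 49-day baseline without cold stress fall during
#' lactation and are flagged as such, so that shortened grazing seasons feed
#' lactating cows on hay.
#'
#' @param grazing_days Length of the grazing season, d.
#' @param hay_days_cold Hay-feeding days under environmental (cold) stress.
#' @param cold_stress_factor Intake multiplier applied on cold-stress days.
#' @param hay_days_dry_base Baseline hay days without cold stress fed to dry
#'   pregnant cows.
#' @return A list of class `season_plan` with fields `grazing_days`,
#'   `hay_days_dry`, `hay_days_lact`, `hay_days_cold`, `cold_stress_factor`.
#' @export
#' @examples
#' season_plan(200)  # baseline: 200 grazing + 49 dry + 115 cold-stress days
#' season_plan(175)  # short season: 25 extra hay days fed during lactation
season_plan <- function(grazing_days = 200, hay_days_cold = 115,
                        cold_stress_factor = 1.05, hay_days_dry_base = 49) {
  hay_nostress <- 364 - grazing_days - hay_days_cold
  if (grazing_days < 0 || hay_nostress < 0) {
    stop("configuration error: grazing and cold-stress days exceed the year",
         call. = FALSE)
  }
  if (cold_stress_factor < 1) {
    stop("configuration error: cold_stress_factor must be >= 1", call. = FALSE)
  }
  plan <- list(
    grazing_days = grazing_days,
    hay_days_dry = min(hay_nostress, hay_days_dry_base),
    hay_days_lact = max(0, hay_nostress - hay_days_dry_base),
    hay_days_cold = hay_days_cold,
    cold_stress_factor = cold_stress_factor
  )
  stopifnot(plan$grazing_days + plan$hay_days_dry + plan$hay_days_lact +
              plan$hay_days_cold == 364)
  structure(plan, class = "season_plan")
}

#' Daily dry-matter intake of a beef cow
#'
#' NRC-style intake prediction from metabolic body weight and forage energy
#' density:
#' `DMI = SBW^0.75 * (0.04997 * NEm^2 + 0.04631) / NEm` kg DM/d for a dry
#' pregnant cow. Nonpregnant cows replace the additive constant 0.04631 with
#' 0.0384; lactating cows add 0.2 kg DM per kg of daily milk yield.
#'
#' @param sbw Body weight entering the intake equation, kg (here the BCS-5
#'   normalized weight).
#' @param nem Net energy for maintenance of the diet, Mcal/kg DM.
#' @param state One of `"dry_pregnant"`, `"nonpregnant"`, `"lactating"`.
#' @param milk_yield Daily milk yield, kg/d; used only for lactating cows.
#' @return Dry-matter intake, kg/d.
#' @export
#' @examples
#' daily_dmi(450, 1.20, "dry_pregnant")
#' daily_dmi(450, 1.43, "lactating", milk_yield = 8)
daily_dmi <- function(sbw, nem,
                      state = c("dry_pregnant", "nonpregnant", "lactating"),
                      milk_yield = 0) {
  state <- match.arg(state)
  if (any(sbw <= 0) || any(nem <= 0)) {
    stop("sbw and nem must be positive", call. = FALSE)
  }
  if (state == "lactating" && any(milk_yield < 0)) {
    stop("milk_yield must be non-negative", call. = FALSE)
  }
  addc <- if (state == "nonpregnant") 0.0384 else 0.04631
  base <- sbw^0.75 * (0.04997 * nem^2 + addc) / nem
  if (state == "lactating") base + 0.2 * milk_yield else base
}

#' Milk yield adjusted for cow age
#'
#' Peak lactation scales with the cow's position on her growth curve:
#' a cow at 85% of mature weight milks 85% of the mature peak.
#'
#' @param age Cow age, yr (>= 2).
#' @param peak_milk Mature peak daily milk yield, kg/d.
#' @return Daily milk yield, kg/d.
#' @export
milk_yield_at_age <- function(age, peak_milk = 8) {
  peak_milk * cow_weight_trajectory(1, age)
}

#' Seasonal forage and hay intake per cow
#'
#' Aggregates daily intake over the production year: the grazing season uses
#' the lactating intake on pasture (grazing coincides with calving and
#' lactation); baseline no-stress hay days use the dry pregnant intake on
#' hay; cold-stress hay days use the dry pregnant intake scaled up by the
#' cold-stress factor; any hay days beyond the baseline (shortened grazing
#' seasons) use the lactating intake on hay.
#'
#' @param dbw Cow body weight (BCS-5 normalized), kg.
#' @param plan A [season_plan()].
#' @param forage A [forage_spec()].
#' @param milk_yield Daily milk yield during lactation, kg/d.
#' @return A list of class `intake_result` with `grazing_dm`, `hay_dm`
#'   (kg DM per cow per season) and `ha_per_cow`.
#' @export
#' @examples
#' seasonal_intake(450, season_plan(200), forage_spec())
seasonal_intake <- function(dbw, plan = season_plan(), forage = forage_spec(),
                            milk_yield = 8) {
  if (!inherits(plan, "season_plan")) {
    stop("configuration error: plan must be a season_plan", call. = FALSE)
  }
  grazing_dm <- plan$grazing_days *
    daily_dmi(dbw, forage$nem_pasture, "lactating", milk_yield)
  hay_dry <- daily_dmi(dbw, forage$nem_hay, "dry_pregnant")
  hay_lact <- daily_dmi(dbw, forage$nem_hay, "lactating", milk_yield)
  hay_dm <- plan$hay_days_dry * hay_dry +
    plan$hay_days_cold * plan$cold_stress_factor * hay_dry +
    plan$hay_days_lact * hay_lact
  structure(list(
    grazing_dm = grazing_dm,
    hay_dm = hay_dm,
    ha_per_cow = stocking_rate(grazing_dm, forage)
  ), class = "intake_result")
}

#' Stocking rate from seasonal grazing intake
#'
#' Land required per cow: seasonal grazed dry matter divided by usable
#' forage production (annual productivity times utilization fraction).
#'
#' @param grazing_dm Grazing-season intake, kg DM per cow.
#' @param forage A [forage_spec()].
#' @return Stocking rate, ha per cow.
#' @export
#' @examples
#' stocking_rate(2167.55, forage_spec(productivity = 5662, utilization = 0.5))
stocking_rate <- function(grazing_dm, forage = forage_spec()) {
  if (any(grazing_dm < 0)) stop("grazing_dm must be non-negative", call. = FALSE)
  usable <- forage$productivity * forage$utilization
  if (usable <= 0) stop("productivity and utilization must be positive",
                        call. = FALSE)
  grazing_dm / usable
}

#' Herd size supported by a land base
#'
#' @param total_land Operation size, ha.
#' @param ha_per_cow Stocking rate, ha per cow.
#' @return Number of cows, as a continuous quantity (per-cow budgets are
#'   linear, so fractional herds keep the value surface smooth).
#' @export
herd_size <- function(total_land, ha_per_cow) {
  if (any(total_land <= 0) || any(ha_per_cow <= 0)) {
    stop("total_land and ha_per_cow must be positive", call. = FALSE)
  }
  total_land / ha_per_cow
}
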