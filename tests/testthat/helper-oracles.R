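# Independent spreadsheet-style oracles: literal arithmetic, no package code.

# NRC-style intake, written out cell-by-cell as a spreadsheet would
oracle_dmi_dry <- function(sbw, nem) {
  (sbw^0.75 * (0.04997 * nem * nem + 0.04631)) / nem
}
oracle_dmi_nonpreg <- function(sbw, nem) {
  (sbw^0.75 * (0.04997 * nem * nem + 0.0384)) / nem
}
oracle_dmi_lact <- function(sbw, nem, milk) {
  oracle_dmi_dry(sbw, nem) + 0.2 * milk
}

# efficiency linear predictor evaluated term by term
oracle_predictor <- function(est, dbw, birth, offset_term, age) {
  est["intercept"] + est["ln_dbw"] * log(dbw) + est["birth_wt"] * birth +
    est[offset_term] + est["age"] * age + est["age2"] * age * age
}

# small scenario config for fast NPV grids
small_scenario <- function(weights = c(430.84, 634.92),
                           grazing = c(175, 200)) {
  cfg <- load_scenario_config()
  cfg$mature_weights <- weights
  cfg$grazing_days_grid <- grazing
  cfg
}
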