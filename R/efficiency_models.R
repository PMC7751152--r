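#' Load a packaged efficiency-coefficient set
#'
#' The package ships fitted regression coefficients for the three
#' biological-efficiency responses of the study herd: CWP (calf weaning
#' weight as a percent of cow body weight), 205-d adjusted weaning weight
#' (WW) and yearling weight (YW). Each model has the same design:
#' intercept, ln(DBW), calf birth weight, calf-sex offsets (heifer, steer),
#' cow age and age squared. Users may point `path` at their own file in the
#' same CSV format (columns `term`, `estimate`).
#'
#' @param response One of `"cwp"`, `"ww"`, `"yw"`.
#' @param path Optional path to a user-supplied coefficient CSV.
#' @return A named list of class `efficiency_coefficients` with elements
#'   `intercept`, `b_ln_dbw`, `b_birth`, `b_heifer`, `b_steer`, `b_age`,
#'   `b_age2` (and, when available, `residual_sd`, `year_sd`, `cow_sd`).
#' @export
#' @examples
#' efficiency_coefficients("cwp")$b_ln_dbw
efficiency_coefficients <- function(response = c("cwp", "ww", "yw"),
                                    path = NULL) {
  response <- match.arg(response)
  if (is.null(path)) {
    path <- system.file("extdata",
                        paste0("coefficients_", response, ".csv"),
                        package = "cowsize", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("intercept", "ln_dbw", "birth_wt", "heifer", "steer", "age", "age2")
  if (!all(need %in% df$term)) {
    stop("coefficient file must define terms: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  est <- stats::setNames(df$estimate, df$term)
  structure(list(
    response = response,
    intercept = est[["intercept"]],
    b_ln_dbw = est[["ln_dbw"]],
    b_birth = est[["birth_wt"]],
    b_heifer = est[["heifer"]],
    b_steer = est[["steer"]],
    b_age = est[["age"]],
    b_age2 = est[["age2"]],
    ci_lower = if ("ci_lower" %in% names(df)) stats::setNames(df$ci_lower, df$term),
    ci_upper = if ("ci_upper" %in% names(df)) stats::setNames(df$ci_upper, df$term)
  ), class = "efficiency_coefficients")
}

#' Evaluate the efficiency linear predictor
#'
#' `intercept + b_ln_dbw*ln(dbw) + b_birth*birth_wt + sex offset +
#'  b_age*age + b_age2*age^2`. Sex is a three-level factor
#' `{base, heifer, steer}`; predictions for study-herd calves always apply
#' an explicit heifer or steer offset.
#'
#' @param dbw Cow BCS-5 normalized body weight, kg (> 0).
#' @param birth_wt Calf birth weight, kg.
#' @param sex `"heifer"`, `"steer"` or `"base"` (omitted reference level).
#' @param age Cow age, yr (>= 1).
#' @param coeffs An [efficiency_coefficients()] set.
#' @return Predicted response on the scale of the coefficient set
#'   (percent for CWP, kg for WW/YW).
#' @export
predict_efficiency <- function(dbw, birth_wt, sex, age, coeffs) {
  if (any(dbw <= 0)) stop("dbw must be positive", call. = FALSE)
  if (any(age < 1)) stop("age must be >= 1", call. = FALSE)
  offset <- vapply(as.character(sex), function(s) {
    switch(s, heifer = coeffs$b_heifer, steer = coeffs$b_steer, base = 0,
           stop("sex must be 'heifer', 'steer' or 'base'", call. = FALSE))
  }, numeric(1), USE.NAMES = FALSE)
  coeffs$intercept + coeffs$b_ln_dbw * log(dbw) + coeffs$b_birth * birth_wt +
    offset + coeffs$b_age * age + coeffs$b_age2 * age^2
}

#' @rdname predict_efficiency
#' @export
predict_cwp <- function(dbw, birth_wt, sex, age,
                        coeffs = efficiency_coefficients("cwp")) {
  predict_efficiency(dbw, birth_wt, sex, age, coeffs)
}

#' @rdname predict_efficiency
#' @export
predict_ww <- function(dbw, birth_wt, sex, age,
                       coeffs = efficiency_coefficients("ww")) {
  predict_efficiency(dbw, birth_wt, sex, age, coeffs)
}

#' @rdname predict_efficiency
#' @export
predict_yw <- function(dbw, birth_wt, sex, age,
                       coeffs = efficiency_coefficients("yw")) {
  predict_efficiency(dbw, birth_wt, sex, age, coeffs)
}

#' Fit a biological-efficiency mixed model to herd records
#'
#' Linear mixed model with fixed effects ln(DBW), calf birth weight, calf
#' sex, cow age and age squared, and crossed random intercepts for year and
#' cow, fitted by REML with [lme4::lmer()]. The CWP response is computed
#' per record as `100 * ww205 / dbw`.
#'
#' Marginal R^2 (fixed effects over total variance) and conditional R^2
#' (fixed plus random over total) follow the standard variance-partition
#' definition for Gaussian mixed models.
#'
#' @param records data.frame of cow-year records with columns `dbw`,
#'   `calf_birth_wt`, `calf_sex`, `age`, `year`, `cow_id` and the response
#'   column (`ww205` or `yw`).
#' @param response One of `"cwp"`, `"ww"`, `"yw"`.
#' @return A list of class `efficiency_fit` with elements `coefficients`
#'   (an `efficiency_coefficients` list including `residual_sd`, `year_sd`,
#'   `cow_sd`), `n_obs`, `marginal_r2`, `conditional_r2`, `ci` (95% Wald
#'   intervals for fixed effects) and the underlying `lmer` fit.
#' @export
fit_efficiency_model <- function(records, response = c("cwp", "ww", "yw")) {
  response <- match.arg(response)
  y <- switch(response,
              cwp = 100 * records$ww205 / records$dbw,
              ww = records$ww205,
              yw = records$yw)
  d <- data.frame(
    y = y,
    ln_dbw = log(records$dbw),
    birth_wt = records$calf_birth_wt,
    sex = factor(records$calf_sex, levels = c("heifer", "steer")),
    age = records$age,
    year = factor(records$year),
    cow_id = factor(records$cow_id)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 50) {
    stop("need >= 50 records with a non-missing response", call. = FALSE)
  }
  if (nlevels(droplevels(d$year)) < 2) {
    stop("degenerate design: only one level of 'year'", call. = FALSE)
  }
  if (nlevels(droplevels(d$cow_id)) < 2) {
    stop("degenerate design: only one level of 'cow_id'", call. = FALSE)
  }
  fit <- lme4::lmer(
    y ~ ln_dbw + birth_wt + sex + age + I(age^2) + (1 | year) + (1 | cow_id),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  var_year <- as.numeric(vc$year)
  var_cow <- as.numeric(vc$cow_id)
  var_resid <- attr(vc, "sc")^2
  # variance explained by fixed effects: variance of the linear predictor
  var_fixed <- stats::var(as.numeric(stats::model.matrix(fit) %*% beta))
  var_total <- var_fixed + var_year + var_cow + var_resid
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  coeffs <- structure(list(
    response = response,
    intercept = unname(beta["(Intercept)"]),
    b_ln_dbw = unname(beta["ln_dbw"]),
    b_birth = unname(beta["birth_wt"]),
    # heifer is the model's reference level: report offsets vs an implicit
    # zero base so predict_efficiency() reproduces fitted values
    b_heifer = 0,
    b_steer = unname(beta["sexsteer"]),
    b_age = unname(beta["age"]),
    b_age2 = unname(beta["I(age^2)"]),
    residual_sd = sqrt(var_resid),
    year_sd = sqrt(var_year),
    cow_sd = sqrt(var_cow)
  ), class = "efficiency_coefficients")
  structure(list(
    coefficients = coeffs,
    n_obs = nrow(d),
    marginal_r2 = var_fixed / var_total,
    conditional_r2 = (var_fixed + var_year + var_cow) / var_total,
    ci = ci,
    fit = fit
  ), class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat("Efficiency mixed model (", x$coefficients$response, "), n = ",
      x$n_obs, "\n", sep = "")
  cat(sprintf("  ln(DBW): %.2f   birth wt: %.3f   steer-heifer: %.2f\n",
              x$coefficients$b_ln_dbw, x$coefficients$b_birth,
              x$coefficients$b_steer))
  cat(sprintf("  age: %.2f  age^2: %.3f\n",
              x$coefficients$b_age, x$coefficients$b_age2))
  cat(sprintf("  SDs  year: %.2f  cow: %.2f  residual: %.2f\n",
              x$coefficients$year_sd, x$coefficients$cow_sd,
              x$coefficients$residual_sd))
  cat(sprintf("  marginal R2 %.3f / conditional R2 %.3f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Weaned kilograms per hectare
#'
#' @param ww205 205-d adjusted weaning weight, kg.
#' @param ha_per_cow Stocking rate, ha per cow (> 0).
#' @return Weaned output per unit land, kg/ha.
#' @export
weaned_kg_per_ha <- function(ww205, ha_per_cow) {
  if (any(ha_per_cow <= 0)) stop("ha_per_cow must be positive", call. = FALSE)
  ww205 / ha_per_cow
}

#' Regression of weaned output per hectare on cow weight
#'
#' Linear regression of per-record WW/ha on DBW with year as a categorical
#' covariate; the slope is reported per 100 kg of cow body weight (the
#' land-basis efficiency contrast: how much less weaned output per hectare
#' each extra 100 kg of cow carries).
#'
#' @param records data.frame with `dbw`, `ww205`, `year` and `ha_per_cow`.
#' @return A list with `slope_per_100kg`, the fitted `lm` object and `n_obs`.
#' @export
fit_output_per_ha <- function(records) {
  d <- data.frame(
    wwha = weaned_kg_per_ha(records$ww205, records$ha_per_cow),
    dbw = records$dbw,
    year = factor(records$year)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fit <- stats::lm(wwha ~ dbw + year, data = d)
  list(slope_per_100kg = 100 * unname(stats::coef(fit)["dbw"]),
       fit = fit, n_obs = nrow(d))
}
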