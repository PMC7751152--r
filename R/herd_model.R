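#' Weight-tier table for cow body-weight classification
#'
#' Eleven half-open weight classes `[lower, upper)` partitioning (0, Inf),
#' used throughout the enterprise-budget analysis. Class 1 is everything
#' below 430.84 kg and class 11 everything from 634.92 kg up; interior
#' boundaries step by 50 lb (22.67--22.68 kg).
#'
#' @return A data.frame with columns `index`, `lower` (kg, inclusive) and
#'   `upper` (kg, exclusive).
#' @export
#' @examples
#' weight_tiers()
weight_tiers <- function() {
  bounds <- c(430.84, 453.51, 476.19, 498.87, 521.54,
              544.22, 566.89, 589.57, 612.24, 634.92)
  data.frame(
    index = 1:11,
    lower = c(0, bounds),
    upper = c(bounds, Inf)
  )
}

#' Normalize cow body weight to body condition score 5
#'
#' Cow weights recorded at weaning are adjusted to a common body condition
#' score (BCS) of 5 so that weight comparisons reflect frame size rather
#' than fleshiness. The adjustment is linear in condition score:
#' `dbw = bw * (1 + f * (5 - bcs))`, i.e. each unit of BCS above 5 removes a
#' fraction `f` of body weight (and each unit below adds it). When BCS is
#' missing the recorded weight is used as-is, matching the handling of the
#' study year without condition records.
#'
#' @param bw Body weight at weaning, kg. Must be positive.
#' @param bcs Body condition score on the 1--9 scale, or `NA` when not
#'   recorded.
#' @param f Fractional weight change per unit of condition score;
#'   default 0.04 (~4% of body weight per score, an NRC-style convention).
#' @return BCS-5 normalized body weight (DBW), kg.
#' @export
#' @examples
#' normalize_to_bcs5(550, 5)   # reference condition: unchanged
#' normalize_to_bcs5(550, 6)   # fleshier cow: adjusted down
#' normalize_to_bcs5(550, NA)  # no record: actual weight used
normalize_to_bcs5 <- function(bw, bcs, f = 0.04) {
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("invalid record: body weight must be positive", call. = FALSE)
  }
  bad <- !is.na(bcs) & (bcs < 1 | bcs > 9)
  if (any(bad)) {
    stop("invalid record: BCS must lie in [1, 9]", call. = FALSE)
  }
  adj <- ifelse(is.na(bcs), 1, 1 + f * (5 - bcs))
  bw * adj
}

#' Assign a cow to its weight tier
#'
#' @param dbw BCS-5 normalized body weight, kg (vectorized). Must be
#'   positive.
#' @param tiers Tier table as returned by [weight_tiers()].
#' @return Integer tier index in 1..11; each weight maps to the unique tier
#'   whose `[lower, upper)` interval contains it.
#' @export
#' @examples
#' assign_weight_tier(c(400, 430.84, 650))
assign_weight_tier <- function(dbw, tiers = weight_tiers()) {
  if (any(!is.finite(dbw)) || any(dbw <= 0)) {
    stop("dbw must be positive", call. = FALSE)
  }
  # findInterval with left-closed intervals: breaks are the tier lowers
  findInterval(dbw, tiers$lower, left.open = FALSE)
}

#' Read cow-year herd records from CSV
#'
#' One row per cow-year with columns `cow_id`, `year`, `age`, `bw`, `bcs`,
#' `calf_sex`, `calf_birth_wt`, `ww205`, `yw`; missing values as empty
#' fields. Rows violating the record invariants (non-positive weights, BCS
#' outside 1--9, age < 1, weaning weight not below cow weight) are dropped
#' with a message. The BCS-5 normalized weight `dbw` is computed on read.
#'
#' @param path Path to the CSV file.
#' @param bcs_adjustment Per-score weight fraction passed to
#'   [normalize_to_bcs5()].
#' @return data.frame of validated cow-year records, including `dbw`.
#' @export
read_herd_csv <- function(path, bcs_adjustment = 0.04) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cow_id", "year", "age", "bw", "bcs", "calf_sex",
                "calf_birth_wt", "ww205", "yw")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("herd file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(df$bw) & df$bw > 0 &
    (is.na(df$bcs) | (df$bcs >= 1 & df$bcs <= 9)) &
    is.finite(df$age) & df$age >= 1 &
    df$calf_sex %in% c("heifer", "steer") &
    (is.na(df$ww205) | df$ww205 < df$bw)
  if (any(!ok)) {
    message(sum(!ok), " record(s) rejected by validation")
  }
  df <- df[ok, , drop = FALSE]
  df$dbw <- normalize_to_bcs5(df$bw, df$bcs, f = bcs_adjustment)
  df
}

#' Summarize a herd of cow-year records
#'
#' Means and standard deviations of normalized cow weight, condition score,
#' weaning and yearling weights (overall and by calf sex), and the herd-mean
#' weaning-weight ratio CWP = 100 * ww205 / dbw. Missing weaning or yearling
#' weights are excluded from their respective summaries.
#'
#' @param records data.frame of cow-year records with at least `dbw`; `bcs`,
#'   `ww205`, `yw`, `calf_sex` are summarized when present.
#' @return A list of class `herd_summary`.
#' @export
summarize_herd <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty input: no herd records to summarize", call. = FALSE)
  }
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    c(mean = mean(x), sd = stats::sd(x), n = length(x))
  }
  by_sex <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(split(x, records$calf_sex), msd)
  }
  cwp <- if (!is.null(records$ww205)) 100 * records$ww205 / records$dbw else NULL
  out <- list(
    n_records = nrow(records),
    dbw = msd(records$dbw),
    bcs = msd(records$bcs),
    ww  = msd(records$ww205),
    ww_by_sex = if (!is.null(records$calf_sex)) by_sex(records$ww205),
    yw  = msd(records$yw),
    yw_by_sex = if (!is.null(records$calf_sex)) by_sex(records$yw),
    cwp = msd(cwp)
  )
  class(out) <- "herd_summary"
  out
}

#' @export
print.herd_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f +/- %.2f (n=%d)", v["mean"], v["sd"], v["n"])
  cat("Herd summary over", x$n_records, "cow-year records\n")
  cat("  DBW, kg :", fmt(x$dbw), "\n")
  if (x$bcs["n"] > 0) cat("  BCS     :", fmt(x$bcs), "\n")
  if (x$ww["n"] > 0)  cat("  WW, kg  :", fmt(x$ww), "\n")
  if (x$yw["n"] > 0)  cat("  YW, kg  :", fmt(x$yw), "\n")
  if (x$cwp["n"] > 0) cat("  CWP, %  :", fmt(x$cwp), "\n")
  invisible(x)
}
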