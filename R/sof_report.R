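# Summary-of-findings arithmetic and side-by-side IPD vs aggregate
# comparison: corresponding absolute risks per 1000, CI-width reduction,
# forest tables.

#' Corresponding absolute risk per 1000
#'
#' GRADE-style summary-of-findings arithmetic: at a stated assumed
#' control-group risk, the corresponding risk under intervention is
#' `assumed x RR`, and its CI bounds come from the CI limits of the
#' relative effect.  Values are rounded half-up to whole persons per
#' 1000; results above 1000 are clipped with a warning.
#'
#' @param assumed_per_1000 assumed control risk per 1000 (0-1000).
#' @param rr pooled risk ratio (point estimate, natural scale).
#' @param ci length-2 numeric: 95% CI of the RR.
#' @return a list: `assumed_risk_per_1000`, `corresponding_risk_per_1000`,
#'   `corresponding_ci_per_1000` (length 2).
#' @export
#' @examples
#' corresponding_risk(150, 1.03, c(0.81, 1.31)) # 155 per 1000 (122 to 197)
corresponding_risk <- function(assumed_per_1000, rr, ci) {
  if (assumed_per_1000 < 0 || assumed_per_1000 > 1000) {
    stop("assumed risk must lie in [0, 1000]", call. = FALSE)
  }
  vals <- round_half_up(assumed_per_1000 * c(rr, ci[1], ci[2]))
  if (any(vals > 1000)) {
    warning("corresponding risk above 1000 per 1000; clipped", call. = FALSE)
    vals <- pmin(vals, 1000)
  }
  list(assumed_risk_per_1000 = assumed_per_1000,
       corresponding_risk_per_1000 = vals[1],
       corresponding_ci_per_1000 = vals[2:3])
}

#' Build a summary-of-findings row from a pooled result
#'
#' @param outcome outcome label.
#' @param assumed_per_1000 assumed control risk per 1000.
#' @param pooled a `pooled_result` on a ratio scale.
#' @return a one-row `data.frame` with assumed and corresponding risks,
#'   the relative effect, `k` and `n_total`.
#' @export
sof_row <- function(outcome, assumed_per_1000, pooled) {
  if (pooled$scale == "smd") {
    stop("summary-of-findings rows need a ratio-scale pooled result",
         call. = FALSE)
  }
  cr <- corresponding_risk(assumed_per_1000, exp(pooled$pooled_estimate),
                           pooled$ci95)
  data.frame(outcome = outcome,
             assumed_risk_per_1000 = cr$assumed_risk_per_1000,
             corresponding_risk_per_1000 = cr$corresponding_risk_per_1000,
             corresponding_ci_low_per_1000 = cr$corresponding_ci_per_1000[1],
             corresponding_ci_high_per_1000 = cr$corresponding_ci_per_1000[2],
             relative_effect = exp(pooled$pooled_estimate),
             relative_ci_low = pooled$ci95[1],
             relative_ci_high = pooled$ci95[2],
             k = pooled$k, n_total = pooled$n_total,
             stringsAsFactors = FALSE)
}

#' Confidence-interval width reduction
#'
#' Percentage by which interval `ci_a` is narrower than the reference
#' interval `ci_b`, computed on the untransformed (ratio) scale:
#' `100 * (width_b - width_a) / width_b`.  Positive values mean `ci_a`
#' is narrower.  Rounded to the nearest integer for display by default
#' (`round = FALSE` returns full precision); a log-scale alternative is
#' available.
#'
#' @param ci_a,ci_b length-2 numeric intervals; `ci_b` is the reference.
#' @param scale `"ratio"` (default) or `"log"`.
#' @param round round to nearest integer percent.
#' @return percent (scalar).
#' @export
#' @examples
#' ci_width_reduction(c(0.81, 1.31), c(0.77, 1.33)) # 11
ci_width_reduction <- function(ci_a, ci_b, scale = c("ratio", "log"),
                               round = TRUE) {
  scale <- match.arg(scale)
  f <- if (scale == "log") log else identity
  wa <- f(ci_a[2]) - f(ci_a[1])
  wb <- f(ci_b[2]) - f(ci_b[1])
  if (wb == 0) stop("reference interval has zero width", call. = FALSE)
  pct <- 100 * (wb - wa) / wb
  if (round) round_half_up(pct) else pct
}

#' Side-by-side comparison of an IPD and an aggregate pool
#'
#' Assembles the numeric comparison reported for each outcome: CI-width
#' reduction of the IPD pool relative to the aggregate pool, difference
#' in I-squared, and differences in trial and participant counts.  No
#' statistical test of the difference is performed.
#'
#' @param ipd,aggregate `pooled_result` objects on the same scale.
#' @param outcome outcome label.
#' @return a list of class `comparison_report`.
#' @export
compare_pools <- function(ipd, aggregate, outcome = NA_character_) {
  if (!identical(ipd$scale, aggregate$scale)) {
    stop("pooled results are on different scales", call. = FALSE)
  }
  structure(list(
    outcome = outcome, ipd = ipd, aggregate = aggregate,
    ci_width_reduction_percent = ci_width_reduction(ipd$ci95,
                                                    aggregate$ci95),
    i2_difference = (ipd$I2_percent %||% NA_real_) -
      (aggregate$I2_percent %||% NA_real_),
    k_difference = ipd$k - aggregate$k,
    n_difference = ipd$n_total - aggregate$n_total
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  transf <- if (x$ipd$scale == "smd") identity else exp
  cat(sprintf("Comparison%s (scale %s):\n",
              if (is.na(x$outcome)) "" else paste0(" for ", x$outcome),
              x$ipd$scale))
  cat(sprintf("  IPD:       %.2f [%.2f, %.2f], k = %d, n = %d, I2 = %s%%\n",
              transf(x$ipd$pooled_estimate), x$ipd$ci95[1], x$ipd$ci95[2],
              x$ipd$k, x$ipd$n_total, fmt_i2(x$ipd$I2_percent)))
  cat(sprintf("  Aggregate: %.2f [%.2f, %.2f], k = %d, n = %d, I2 = %s%%\n",
              transf(x$aggregate$pooled_estimate), x$aggregate$ci95[1],
              x$aggregate$ci95[2], x$aggregate$k, x$aggregate$n_total,
              fmt_i2(x$aggregate$I2_percent)))
  cat(sprintf("  IPD 95%% CI %d%% narrower; delta I2 = %s points; delta k = %d; delta n = %d\n",
              x$ci_width_reduction_percent,
              if (is.na(x$i2_difference)) "NA" else
                sprintf("%d", round(x$i2_difference)),
              x$k_difference, x$n_difference))
  invisible(x)
}

fmt_i2 <- function(i2) if (is.na(i2)) "NA" else sprintf("%d", round(i2))

#' Forest-table data
#'
#' One row per trial (natural-scale estimate, CI, weight percent) plus a
#' pooled row, suitable for plotting a forest diagram.  Row order follows
#' the input estimates; weights come from the pooled result and sum to
#' 100.
#'
#' @param estimates the stacked [effect_estimate()] frame that was pooled.
#' @param pooled the matching `pooled_result`.
#' @return a `data.frame` with columns `trial_id`, `estimate`, `ci_low`,
#'   `ci_high`, `weight_percent`, `row_type`.
#' @export
forest_table <- function(estimates, pooled) {
  missing_ids <- setdiff(estimates$trial_id, names(pooled$weights))
  if (length(missing_ids) > 0) {
    stop("estimate(s) absent from pooled weights: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  transf <- if (pooled$scale == "smd") identity else exp
  rows <- data.frame(
    trial_id = estimates$trial_id,
    estimate = transf(estimates$estimate),
    ci_low = estimates$ci_low,
    ci_high = estimates$ci_high,
    weight_percent = unname(pooled$weights[estimates$trial_id]),
    row_type = "trial",
    stringsAsFactors = FALSE
  )
  pooled_row <- data.frame(
    trial_id = "POOLED",
    estimate = transf(pooled$pooled_estimate),
    ci_low = pooled$ci95[1], ci_high = pooled$ci95[2],
    weight_percent = 100, row_type = "pooled",
    stringsAsFactors = FALSE
  )
  rbind(rows, pooled_row)
}
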