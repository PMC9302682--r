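# Per-trial effect estimates from aggregate summaries: risk ratios,
# standardized mean differences, and log hazard ratios reconstructed from
# published confidence intervals.

#' Construct an effect-estimate row
#'
#' Effect estimates are one-row data frames (class `effect_estimate`) so
#' that collections of them can be stacked with `rbind()` and written as
#' CSV.  `estimate` and `se` are on the stated analysis scale (`log_rr`,
#' `log_hr`, `log_or` or `smd`); `ci_low`/`ci_high` are on the natural
#' (back-transformed) scale for the log scales.
#'
#' @param trial_id,outcome identifiers.
#' @param scale one of `"log_rr"`, `"log_hr"`, `"smd"`, `"log_or"`.
#' @param estimate,se effect and standard error on the analysis scale.
#' @param n_total,events_total totals (events may be `NA`).
#' @param adjusted logical: covariate-adjusted estimate?
#' @param covariates names of adjustment covariates.
#' @param source provenance: `"aggregate"`, `"ipd_stage1"` or `"cace"`.
#' @param converged logical; `FALSE` marks an inestimable or
#'   non-converged fit whose `estimate`/`se` may be `NA`.
#' @param note free-text provenance (e.g. continuity rule applied).
#' @return a one-row `data.frame` of class `effect_estimate`.
#' @export
effect_estimate <- function(trial_id = NA_character_,
                            outcome = NA_character_,
                            scale = c("log_rr", "log_hr", "smd", "log_or"),
                            estimate = NA_real_, se = NA_real_,
                            n_total = NA_integer_, events_total = NA_integer_,
                            adjusted = FALSE, covariates = character(0),
                            source = c("aggregate", "ipd_stage1", "cace"),
                            converged = TRUE, note = NA_character_) {
  scale <- match.arg(scale)
  source <- match.arg(source)
  if (converged && !is.na(se) && se <= 0) {
    stop("standard error must be positive", call. = FALSE)
  }
  transf <- if (scale == "smd") identity else exp
  est <- data.frame(
    trial_id = as.character(trial_id), outcome = as.character(outcome),
    scale = scale, estimate = estimate, se = se,
    ci_low = if (is.na(estimate) || is.na(se)) NA_real_ else
      transf(estimate - Z975 * se),
    ci_high = if (is.na(estimate) || is.na(se)) NA_real_ else
      transf(estimate + Z975 * se),
    n_total = as.integer(n_total), events_total = as.integer(events_total),
    adjusted = adjusted,
    covariates = paste(covariates, collapse = "+"),
    source = source, converged = converged, note = as.character(note),
    stringsAsFactors = FALSE
  )
  class(est) <- c("effect_estimate", "data.frame")
  est
}

#' Risk ratio from a 2x2 table of counts
#'
#' Computes the unadjusted risk ratio on the log scale with the standard
#' large-sample (Wald) standard error
#' \deqn{\widehat{se} = \sqrt{1/a - 1/n_1 + 1/c - 1/n_0}.}
#' If any of the four cells `a`, `c`, `n1 - a`, `n0 - c` is zero, 0.5 is
#' added to all four cells first (continuity rule `"constant"`, the usual
#' meta-analytic convention; the rule applied is recorded in the
#' estimate's `note`).  A trial with zero events in both arms is flagged
#' inestimable (`converged = FALSE`) and is expected to be excluded from
#' pooling rather than corrected.
#'
#' @param events_treat,n_treat,events_ctrl,n_ctrl per-arm events and sizes.
#' @param continuity continuity rule; only `"constant"` (add 0.5) defined.
#' @param trial_id,outcome carried into the estimate row.
#' @return an [effect_estimate()] row on scale `log_rr`.
#' @export
#' @examples
#' # single-trial food-allergy contrast: 15/482 vs 6/494
#' rr <- rr_from_counts(15, 482, 6, 494)
#' round(exp(rr$estimate), 2) # 2.56
#' round(c(rr$ci_low, rr$ci_high), 2) # 1.00, 6.55
rr_from_counts <- function(events_treat, n_treat, events_ctrl, n_ctrl,
                           continuity = "constant",
                           trial_id = NA_character_, outcome = NA_character_) {
  continuity <- match.arg(continuity, "constant")
  if (n_treat <= 0 || n_ctrl <= 0) stop("arm sizes must be positive", call. = FALSE)
  if (events_treat > n_treat || events_ctrl > n_ctrl) {
    stop("events cannot exceed arm size", call. = FALSE)
  }
  if (events_treat == 0 && events_ctrl == 0) {
    return(effect_estimate(trial_id, outcome, "log_rr",
                           n_total = n_treat + n_ctrl, events_total = 0L,
                           source = "aggregate", converged = FALSE,
                           note = "double-zero: inestimable"))
  }
  a <- events_treat; c <- events_ctrl; n1 <- n_treat; n0 <- n_ctrl
  note <- NA_character_
  if (a == 0 || c == 0 || (n1 - a) == 0 || (n0 - c) == 0) {
    a <- a + 0.5; c <- c + 0.5; n1 <- n1 + 1; n0 <- n0 + 1
    note <- "continuity: +0.5 to all cells"
  }
  est <- log((a / n1) / (c / n0))
  se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
  effect_estimate(trial_id, outcome, "log_rr", est, se,
                  n_total = n_treat + n_ctrl,
                  events_total = events_treat + events_ctrl,
                  source = "aggregate", note = note)
}

#' Standardized mean difference (Hedges' g) from summary statistics
#'
#' Cohen's d from the pooled standard deviation, corrected for
#' small-sample bias with Hedges' factor `J = 1 - 3 / (4N - 9)`, with
#' the usual large-sample variance
#' `N / (n_t n_c) + g^2 / (2N)`, `N = n_t + n_c`.
#'
#' @param mean_treat,sd_treat,n_treat,mean_ctrl,sd_ctrl,n_ctrl per-arm
#'   summaries (`sd > 0`, `n >= 2`).
#' @param trial_id,outcome carried into the estimate row.
#' @return an [effect_estimate()] row on scale `smd`.
#' @export
smd_from_summary <- function(mean_treat, sd_treat, n_treat,
                             mean_ctrl, sd_ctrl, n_ctrl,
                             trial_id = NA_character_,
                             outcome = NA_character_) {
  if (sd_treat <= 0 || sd_ctrl <= 0) stop("standard deviations must be positive", call. = FALSE)
  if (n_treat < 2 || n_ctrl < 2) stop("arm sizes must be >= 2", call. = FALSE)
  N <- n_treat + n_ctrl
  sp <- sqrt(((n_treat - 1) * sd_treat^2 + (n_ctrl - 1) * sd_ctrl^2) /
               (N - 2))
  if (sp == 0) stop("pooled standard deviation is zero", call. = FALSE)
  d <- (mean_treat - mean_ctrl) / sp
  J <- 1 - 3 / (4 * N - 9)
  g <- d * J
  se <- sqrt(N / (n_treat * n_ctrl) + g^2 / (2 * N))
  effect_estimate(trial_id, outcome, "smd", g, se, n_total = N,
                  source = "aggregate")
}

#' Log hazard ratio reconstructed from a reported HR and 95% CI
#'
#' Back-calculates the log-scale standard error from the printed interval:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param hr reported hazard ratio (> 0).
#' @param ci_low,ci_high reported 95% CI limits (`ci_low < hr < ci_high`).
#' @param trial_id,outcome carried into the estimate row.
#' @return an [effect_estimate()] row on scale `log_hr`.
#' @export
loghr_from_reported <- function(hr, ci_low, ci_high,
                                trial_id = NA_character_,
                                outcome = NA_character_) {
  if (any(c(hr, ci_low, ci_high) <= 0)) {
    stop("hazard ratio and CI limits must be positive", call. = FALSE)
  }
  if (!(ci_low < hr && hr < ci_high)) {
    stop("CI must bracket the point estimate", call. = FALSE)
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * Z975)
  effect_estimate(trial_id, outcome, "log_hr", log(hr), se,
                  source = "aggregate",
                  note = "se back-calculated from reported CI")
}

#' Write / read effect-estimate tables
#'
#' @param estimates a stacked `effect_estimate` data frame.
#' @param path CSV path.
#' @return the data frame (read) or `path` invisibly (write).
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  class(df) <- c("effect_estimate", "data.frame")
  df
}
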