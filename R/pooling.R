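# Inverse-variance pooling (stage 2 of the two-stage IPD analysis and the
# aggregate meta-analysis), heterogeneity statistics, leave-one-out
# dissection, subgroup pools and mixed IPD + aggregate sensitivity pools.

#' Inverse-variance pooling with DerSimonian-Laird heterogeneity
#'
#' Pools per-trial effect estimates (all on a common scale) with
#' inverse-variance weights.  Fixed-effect weights are \eqn{w_i = 1/se_i^2};
#' Cochran's \eqn{Q = \sum w_i (y_i - \hat y_{fixed})^2} with `k - 1`
#' degrees of freedom; the DerSimonian-Laird moment estimator
#' \deqn{\tau^2 = \max\left(0, \frac{Q - (k-1)}{\sum w - \sum w^2 / \sum w}\right)}
#' gives random-effects weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}.  The 95%
#' CI is Wald-normal, back-transformed to the natural scale for the log
#' scales.  \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} quantifies the
#' percentage of variability beyond chance; it is undefined for `k = 1`
#' (single-study "pools" are legal and return the input estimate with
#' heterogeneity fields `NA`).
#'
#' @param estimates a stacked [effect_estimate()] data frame; all rows must
#'   share one `scale` and be converged (filter first).
#' @param model `"random_DL"` (default) or `"fixed"`.
#' @param tau2_method `"DL"` (DerSimonian-Laird moment estimator, the
#'   default and the reporting surface) or `"REML"` (restricted maximum
#'   likelihood, offered for sensitivity analyses).
#' @return an object of class `pooled_result`: a list with `scale`, `k`,
#'   `n_total`, `pooled_estimate` and `se` on the analysis scale, `ci95`
#'   (natural scale for log scales), `tau2`, `Q`, `df`, `p_het`,
#'   `I2_percent`, `weights` (percent, named by trial), `model`, and
#'   provenance flags.
#' @export
#' @examples
#' e1 <- rr_from_counts(15, 482, 6, 494, trial_id = "A")
#' pool_inverse_variance(e1) # single-study pool: passthrough
pool_inverse_variance <- function(estimates,
                                  model = c("random_DL", "fixed"),
                                  tau2_method = c("DL", "REML")) {
  model <- match.arg(model)
  tau2_method <- match.arg(tau2_method)
  if (is.null(estimates) || nrow(estimates) == 0) {
    stop("no estimates to pool", call. = FALSE)
  }
  if (length(unique(estimates$scale)) != 1) {
    stop("estimates mix scales: ",
         paste(unique(estimates$scale), collapse = ", "), call. = FALSE)
  }
  if (!all(estimates$converged)) {
    stop("non-converged estimates included; filter before pooling",
         call. = FALSE)
  }
  scale <- estimates$scale[1]
  y <- estimates$estimate
  se <- estimates$se
  k <- length(y)
  ids <- if (!is.null(estimates$trial_id)) estimates$trial_id else
    as.character(seq_len(k))
  w <- 1 / se^2
  y_fixed <- sum(w * y) / sum(w)
  if (k >= 2) {
    Q <- sum(w * (y - y_fixed)^2)
    df <- k - 1
    p_het <- stats::pchisq(Q, df, lower.tail = FALSE)
    tau2 <- if (tau2_method == "DL") {
      max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
    } else {
      reml_tau2(y, se^2)
    }
    I2 <- max(0, (Q - df) / Q) * 100
  } else {
    Q <- NA_real_; df <- 0L; p_het <- NA_real_
    tau2 <- 0; I2 <- NA_real_
  }
  wr <- if (model == "random_DL") 1 / (se^2 + tau2) else w
  pooled <- sum(wr * y) / sum(wr)
  se_pooled <- 1 / sqrt(sum(wr))
  transf <- if (scale == "smd") identity else exp
  ci <- transf(pooled + c(-1, 1) * Z975 * se_pooled)
  adj <- unique(estimates$adjusted)
  res <- structure(list(
    scale = scale, k = k,
    n_total = sum(estimates$n_total, na.rm = TRUE),
    pooled_estimate = pooled, se = se_pooled, ci95 = ci,
    tau2 = tau2, Q = Q, df = df, p_het = p_het, I2_percent = I2,
    weights = stats::setNames(100 * wr / sum(wr), ids),
    model = model, tau2_method = tau2_method,
    sources = unique(estimates$source),
    mixed_adjustment = length(adj) > 1,
    trial_ids = ids
  ), class = "pooled_result")
  res
}

# REML estimate of the between-trial variance, profiled over tau2 by
# golden-section search; used only behind the tau2_method flag.
reml_tau2 <- function(y, v) {
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  upper <- max(stats::var(y) * 4, max(v) * 10, 1e-3)
  stats::optimize(nll, c(0, upper))$minimum
}

#' @export
print.pooled_result <- function(x, ...) {
  transf <- if (x$scale == "smd") identity else exp
  cat(sprintf("Pooled %s (%s, tau2 via %s): %s = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$scale, x$model, x$tau2_method,
              if (x$scale == "smd") "SMD" else "ratio",
              transf(x$pooled_estimate), x$ci95[1], x$ci95[2]))
  cat(sprintf("k = %d trials, n = %d participants\n", x$k, x$n_total))
  if (x$k >= 2) {
    cat(sprintf("Heterogeneity: Q = %.3f (df = %d, p = %.3f), tau2 = %.4f, I2 = %d%%\n",
                x$Q, x$df, x$p_het, x$tau2, round(x$I2_percent)))
  } else {
    cat("Heterogeneity: not applicable (single study)\n")
  }
  invisible(x)
}

#' Leave-one-out heterogeneity dissection
#'
#' Re-pools the estimates omitting each trial in turn, to locate trials
#' that drive heterogeneity — e.g. a single deviant trial whose removal
#' brings I-squared down to zero.  Reports the omission that minimizes
#' I-squared (ties broken by smallest Q).
#'
#' @param estimates as in [pool_inverse_variance()]; `k >= 2` required.
#' @param ... passed on to [pool_inverse_variance()].
#' @return a list of class `loo_result`: `results` (named list of
#'   `pooled_result`, one per omitted trial), `I2_without` (named vector),
#'   and `min_I2_trial` (the I-squared-minimizing omission).
#' @export
leave_one_out <- function(estimates, ...) {
  if (nrow(estimates) < 2) stop("leave-one-out needs k >= 2 trials", call. = FALSE)
  ids <- estimates$trial_id
  results <- lapply(seq_len(nrow(estimates)), function(i) {
    pool_inverse_variance(estimates[-i, , drop = FALSE], ...)
  })
  names(results) <- ids
  i2 <- vapply(results, function(r) {
    if (is.na(r$I2_percent)) 0 else r$I2_percent
  }, numeric(1))
  qs <- vapply(results, function(r) if (is.na(r$Q)) 0 else r$Q, numeric(1))
  best <- ids[order(i2, qs)][1]
  structure(list(results = results, I2_without = i2, min_I2_trial = best),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-out I2 (%) by omitted trial:\n")
  print(round(x$I2_without, 1))
  cat("I2-minimizing omission:", x$min_I2_trial, "\n")
  invisible(x)
}

#' Pool IPD-derived and aggregate estimates together
#'
#' Sensitivity pooling that combines stage-1 IPD estimates with aggregate
#' estimates from trials that did not supply IPD.  Trial identifiers must
#' be disjoint across sources; adjusted and unadjusted estimates may be
#' mixed, and the result records this in `mixed_adjustment`.
#'
#' @param ipd_estimates,aggregate_estimates stacked [effect_estimate()]
#'   frames with disjoint `trial_id`s on the same outcome and scale.
#' @param ... passed on to [pool_inverse_variance()].
#' @return a `pooled_result`.
#' @export
pool_mixed_sources <- function(ipd_estimates, aggregate_estimates, ...) {
  dup <- intersect(ipd_estimates$trial_id, aggregate_estimates$trial_id)
  if (length(dup) > 0) {
    stop("trial(s) present in both sources: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  pool_inverse_variance(rbind(ipd_estimates, aggregate_estimates), ...)
}

#' Subgroup pooling
#'
#' Pools independently within trial subgroups (e.g. high-risk versus
#' general-population trials).  Labels without any trial are dropped with
#' a warning.
#'
#' @param estimates stacked [effect_estimate()] frame.
#' @param grouping named character vector mapping `trial_id` to a label;
#'   every trial must be labelled.
#' @param ... passed on to [pool_inverse_variance()].
#' @return a named list of `pooled_result`, one per label.
#' @export
subgroup_pool <- function(estimates, grouping, ...) {
  unlabelled <- setdiff(estimates$trial_id, names(grouping))
  if (length(unlabelled) > 0) {
    stop("unlabelled trial(s): ", paste(unlabelled, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(unname(grouping))
  res <- list()
  for (lab in labels) {
    sel <- estimates$trial_id %in% names(grouping)[grouping == lab]
    if (!any(sel)) {
      warning("subgroup '", lab, "' contains no trials; omitted",
              call. = FALSE)
      next
    }
    res[[lab]] <- pool_inverse_variance(estimates[sel, , drop = FALSE], ...)
  }
  res
}
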