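# Stage 1 of the two-stage IPD meta-analysis: per-trial regression models
# on participant data, with convergence and estimability diagnostics.
#
# Binary outcomes use a binomial GLM with log link so the treatment
# coefficient is an adjusted log risk ratio.  Log-binomial fits are the
# known fragile step (the likelihood maximum can sit on the boundary of
# the parameter space); the documented protocol is: IRLS from fixed
# starting values (log overall event rate, slopes 0), epsilon 1e-8,
# 100 iterations; on failure, modified Poisson regression with a robust
# information-sandwich (HC0) variance, recorded in provenance.  Separation
# is flagged when a coefficient magnitude exceeds 10 on the log scale.

SEPARATION_LIMIT <- 10

stage1_covariates <- function(adjust, high_risk_only) {
  adjust <- intersect(adjust, c("sex", "family_history_atopy"))
  if (high_risk_only) adjust <- setdiff(adjust, "family_history_atopy")
  adjust
}

# Shared log-binomial fitting protocol.  Returns list(coefs, vcov,
# converged, fallback).
fit_log_binomial <- function(formula, data) {
  y <- stats::model.response(stats::model.frame(formula, data))
  start <- c(log(max(mean(y), 1e-8)),
             rep(0, ncol(stats::model.matrix(formula, data)) - 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm(formula, data = data,
                                family = stats::binomial(link = "log"),
                                start = start,
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL
  )
  if (!is.null(fit) && fit$converged &&
      all(abs(stats::coef(fit)) < SEPARATION_LIMIT, na.rm = TRUE) &&
      !anyNA(stats::coef(fit))) {
    return(list(coefs = stats::coef(fit), vcov = stats::vcov(fit),
                converged = TRUE, fallback = FALSE))
  }
  # Modified Poisson fallback: consistent for the RR with a robust
  # variance (the binomial outcome makes the Poisson variance wrong, so
  # a sandwich estimator is required).
  pfit <- tryCatch(
    suppressWarnings(stats::glm(formula, data = data,
                                family = stats::poisson(link = "log"),
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL
  )
  if (is.null(pfit) || !pfit$converged || anyNA(stats::coef(pfit)) ||
      any(abs(stats::coef(pfit)) >= SEPARATION_LIMIT)) {
    return(list(coefs = NULL, vcov = NULL, converged = FALSE,
                fallback = TRUE))
  }
  list(coefs = stats::coef(pfit), vcov = sandwich::vcovHC(pfit, type = "HC0"),
       converged = TRUE, fallback = TRUE)
}

#' Stage-1 adjusted risk ratio for a binary outcome
#'
#' Fits, within one trial, a binomial regression with log link of the
#' resolved outcome on treatment + sex (+ family history of atopy unless
#' the trial enrolled a high-risk population only, in which case family
#' history is constant by design).  The treatment coefficient is the
#' adjusted log risk ratio with its model-based standard error.
#' Participants missing the outcome or any included covariate are
#' excluded complete-case and counted.
#'
#' @param participants one trial's participant records.
#' @param outcome outcome name as in [aggregate_from_participants()];
#'   `"eczema"` is resolved through the diagnostic hierarchy first.
#' @param adjust adjustment covariates; subset of
#'   `c("sex", "family_history_atopy")`.
#' @param high_risk_only if `TRUE`, family history is dropped from the
#'   adjustment set (it is 1 for everyone by design).
#' @return an object of class `stage1_fit`: list with `effect` (an
#'   [effect_estimate()] row, `source = "ipd_stage1"`), `model`,
#'   `adjusted_for`, `n_used`, `n_excluded_missing`, `n_outcome_missing`,
#'   `converged`, `separation_detected`, `fallback_poisson`.
#' @export
fit_binary_stage1 <- function(participants, outcome = "eczema",
                              adjust = c("sex", "family_history_atopy"),
                              high_risk_only = FALSE) {
  adjust <- stage1_covariates(adjust, high_risk_only)
  y <- outcome_values(participants, outcome)
  dat <- data.frame(y = y, treat = participants$arm)
  for (cv in adjust) dat[[cv]] <- participants[[cv]]
  n_outcome_missing <- sum(is.na(dat$y))
  cc <- stats::complete.cases(dat)
  n_excluded_missing <- sum(!cc) - n_outcome_missing
  dat <- dat[cc, , drop = FALSE]
  trial_id <- unique(participants$trial_id)[1]

  base <- list(model = "binomial_log", adjusted_for = adjust,
               n_used = nrow(dat), n_excluded_missing = n_excluded_missing,
               n_outcome_missing = n_outcome_missing)
  inestimable <- function(why, separation = FALSE) {
    structure(c(base, list(
      effect = effect_estimate(trial_id, outcome, "log_rr",
                               n_total = nrow(dat),
                               events_total = as.integer(sum(dat$y)),
                               adjusted = TRUE, covariates = adjust,
                               source = "ipd_stage1", converged = FALSE,
                               note = why),
      converged = FALSE, separation_detected = separation,
      fallback_poisson = FALSE)), class = "stage1_fit")
  }
  if (nrow(dat) == 0 || sum(dat$y) == 0 || sum(dat$y) == nrow(dat)) {
    return(inestimable("all events or no events: inestimable"))
  }
  rhs <- paste(c("treat", adjust), collapse = " + ")
  fit <- fit_log_binomial(stats::as.formula(paste("y ~", rhs)), dat)
  if (!fit$converged) {
    sep <- !is.null(fit$coefs) &&
      any(abs(fit$coefs) >= SEPARATION_LIMIT, na.rm = TRUE)
    return(inestimable("stage 1 model did not converge", separation = sep))
  }
  b <- fit$coefs[["treat"]]
  se <- sqrt(fit$vcov["treat", "treat"])
  sep <- abs(b) >= SEPARATION_LIMIT
  eff <- effect_estimate(trial_id, outcome, "log_rr", b, se,
                         n_total = nrow(dat),
                         events_total = as.integer(sum(dat$y)),
                         adjusted = length(adjust) > 0, covariates = adjust,
                         source = "ipd_stage1",
                         note = if (fit$fallback)
                           "fallback: modified Poisson + HC0 sandwich" else
                           NA_character_)
  structure(c(base, list(effect = eff, converged = TRUE,
                         separation_detected = sep,
                         fallback_poisson = fit$fallback)),
            class = "stage1_fit")
}

#' Stage-1 discrete-time hazard ratio for time to eczema onset
#'
#' Onset times derived from visit schedules are interval-censored, so the
#' model is a discrete-time survival regression: each participant is
#' expanded into one record per visit interval at risk, and a binomial
#' regression with complementary log-log link of the interval event
#' indicator on treatment + covariates + an interval factor is fitted.
#' Under proportional hazards in continuous time, the treatment
#' coefficient is the log hazard ratio.
#'
#' @inheritParams fit_binary_stage1
#' @return a `stage1_fit` with `model = "binomial_cloglog"` and the effect
#'   on scale `log_hr`.
#' @export
fit_tte_stage1 <- function(participants,
                           adjust = c("sex", "family_history_atopy"),
                           high_risk_only = FALSE) {
  adjust <- stage1_covariates(adjust, high_risk_only)
  tte <- derive_time_to_event(participants)
  trial_id <- unique(participants$trial_id)[1]
  keep <- !is.na(tte$time_days)
  for (cv in adjust) keep <- keep & !is.na(participants[[cv]])
  n_excluded_missing <- sum(!keep & !is.na(tte$time_days))
  n_outcome_missing <- sum(is.na(tte$time_days))

  # person-period expansion over each participant's own visit grid
  rows <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    v <- participants$visit_ages_days[[i]]
    ix <- participants$eczema_first_visit_index[i]
    last <- if (is.na(ix)) length(v) else ix
    j <- j + 1
    rec <- data.frame(
      interval_end = v[seq_len(last)],
      event = c(rep(0, last - 1), as.numeric(!is.na(ix))),
      treat = participants$arm[i]
    )
    for (cv in adjust) rec[[cv]] <- participants[[cv]][i]
    rows[[j]] <- rec
  }
  pp <- do.call(rbind, rows)
  base <- list(model = "binomial_cloglog", adjusted_for = adjust,
               n_used = sum(keep), n_excluded_missing = n_excluded_missing,
               n_outcome_missing = n_outcome_missing)
  inestimable <- function(why, separation = FALSE) {
    structure(c(base, list(
      effect = effect_estimate(trial_id, "time_to_eczema", "log_hr",
                               n_total = sum(keep),
                               adjusted = TRUE, covariates = adjust,
                               source = "ipd_stage1", converged = FALSE,
                               note = why),
      converged = FALSE, separation_detected = separation,
      fallback_poisson = FALSE)), class = "stage1_fit")
  }
  if (is.null(pp) || nrow(pp) == 0 || sum(pp$event) == 0) {
    return(inestimable("no events: inestimable"))
  }
  rhs <- paste(c("treat", adjust, "factor(interval_end)"), collapse = " + ")
  fit <- tryCatch(
    suppressWarnings(stats::glm(stats::as.formula(paste("event ~", rhs)),
                                data = pp,
                                family = stats::binomial(link = "cloglog"),
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || is.na(stats::coef(fit)[["treat"]])) {
    return(inestimable("stage 1 model did not converge"))
  }
  b <- stats::coef(fit)[["treat"]]
  se <- sqrt(stats::vcov(fit)["treat", "treat"])
  sep <- abs(b) >= SEPARATION_LIMIT
  if (sep) {
    return(inestimable("separation on treatment", separation = TRUE))
  }
  eff <- effect_estimate(trial_id, "time_to_eczema", "log_hr", b, se,
                         n_total = sum(keep),
                         events_total = as.integer(sum(pp$event)),
                         adjusted = length(adjust) > 0, covariates = adjust,
                         source = "ipd_stage1")
  structure(c(base, list(effect = eff, converged = TRUE,
                         separation_detected = FALSE,
                         fallback_poisson = FALSE)),
            class = "stage1_fit")
}

#' Stage-1 treatment-by-covariate interaction
#'
#' Adds a binary effect modifier and its product with treatment to the
#' stage-1 log-link binomial model; the interaction coefficient is the
#' log ratio of risk ratios between modifier strata.  Before fitting, the
#' four modifier-by-arm cells are inspected: a cell in which every
#' participant (or none) has the outcome makes the interaction predict
#' the outcome perfectly, so the fit is flagged (`perfect_prediction`)
#' instead of returning a spurious estimate.
#'
#' Modifiers: `"age_at_initiation"` dichotomized at `threshold` days
#' (default < 4 versus >= 4 days of age at treatment initiation),
#' `"flg"` (0 versus 1-2 FLG mutations), `"family_history"`.
#'
#' @inheritParams fit_binary_stage1
#' @param modifier one of `"age_at_initiation"`, `"flg"`,
#'   `"family_history"`.
#' @param threshold dichotomization threshold in days for
#'   `age_at_initiation` (modifier = 1 when age < threshold).
#' @return an object of class `interaction_fit`: `interaction_log_rr`,
#'   `se`, `modifier`, `converged`, `perfect_prediction`, `cells`
#'   (events/n per modifier-by-arm cell), and `effect` (an
#'   [effect_estimate()] row for pooling).
#' @export
fit_interaction_stage1 <- function(participants, modifier,
                                   outcome = "eczema", threshold = 4,
                                   adjust = c("sex", "family_history_atopy"),
                                   high_risk_only = FALSE) {
  modifier <- match.arg(modifier,
                        c("age_at_initiation", "flg", "family_history"))
  m <- switch(modifier,
    age_at_initiation = as.numeric(participants$age_at_initiation_days < threshold),
    flg = participants$flg_mutations,
    family_history = participants$family_history_atopy
  )
  adjust <- stage1_covariates(adjust, high_risk_only)
  if (modifier == "family_history") {
    adjust <- setdiff(adjust, "family_history_atopy")
  }
  y <- outcome_values(participants, outcome)
  dat <- data.frame(y = y, treat = participants$arm, m = m)
  for (cv in adjust) dat[[cv]] <- participants[[cv]]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  trial_id <- unique(participants$trial_id)[1]

  out <- function(est = NA_real_, se = NA_real_, converged = FALSE,
                  perfect = FALSE, cells = NULL, note = NA_character_) {
    eff <- effect_estimate(trial_id, paste0(outcome, ":", modifier),
                           "log_rr", est, se, n_total = nrow(dat),
                           adjusted = length(adjust) > 0, covariates = adjust,
                           source = "ipd_stage1", converged = converged,
                           note = note)
    structure(list(interaction_log_rr = est, se = se, modifier = modifier,
                   converged = converged, perfect_prediction = perfect,
                   cells = cells, effect = eff),
              class = "interaction_fit")
  }
  if (length(unique(dat$m)) < 2) {
    return(out(note = "modifier constant: inestimable"))
  }
  if (any(table(dat$treat, dat$m) == 0)) {
    return(out(note = "empty modifier-by-arm cell: inestimable"))
  }
  cells <- stats::aggregate(y ~ treat + m, data = dat,
                            FUN = function(z) c(events = sum(z), n = length(z)))
  cells <- data.frame(treat = cells$treat, m = cells$m,
                      events = cells$y[, "events"], n = cells$y[, "n"])
  if (any(cells$events == 0 | cells$events == cells$n)) {
    return(out(perfect = TRUE, cells = cells,
               note = "a modifier-by-arm cell has 0% or 100% events: the interaction predicts the outcome perfectly"))
  }
  rhs <- paste(c("treat", "m", "treat:m", adjust), collapse = " + ")
  fit <- fit_log_binomial(stats::as.formula(paste("y ~", rhs)), dat)
  if (!fit$converged) {
    return(out(cells = cells, note = "interaction model did not converge"))
  }
  b <- fit$coefs[["treat:m"]]
  se <- sqrt(fit$vcov["treat:m", "treat:m"])
  out(est = b, se = se, converged = TRUE, cells = cells,
      note = if (fit$fallback) "fallback: modified Poisson + HC0 sandwich"
             else NA_character_)
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("Stage-1 %s fit (%s): n_used = %d, excluded (covariates) = %d, outcome missing = %d\n",
              x$model,
              if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = " + ")
              else "unadjusted",
              x$n_used, x$n_excluded_missing, x$n_outcome_missing))
  if (x$converged) {
    transf <- if (x$effect$scale == "smd") identity else exp
    cat(sprintf("  %s = %.3f, 95%% CI [%.3f, %.3f]%s\n",
                toupper(sub("log_", "", x$effect$scale)),
                transf(x$effect$estimate), x$effect$ci_low, x$effect$ci_high,
                if (isTRUE(x$fallback_poisson)) " (Poisson fallback)" else ""))
  } else {
    cat("  not estimable:", x$effect$note, "\n")
  }
  invisible(x)
}
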