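test_that("adjusted log-binomial estimates recover the generator truth", {
  cfg <- trial_config("T", n = 20000, baseline_risk = 0.10,
                      complier_rr = 0.7, compliance_rate = 1,
                      sex_rr = 1.2, famhist_rr = 1.8, flg_rr = 2,
                      covariate_missing_rate = 0.02,
                      outcome_missing_rate = 0.02)
  d <- generate_trial(cfg, 14)
  fit <- fit_binary_stage1(d)
  expect_true(fit$converged)
  expect_false(fit$fallback_poisson)
  expect_lt(abs(fit$effect$estimate - log(0.7)), 3 * fit$effect$se)
  expect_equal(fit$effect$source, "ipd_stage1")
  expect_true(fit$effect$adjusted)
  # complete-case accounting
  expect_equal(fit$n_used + fit$n_excluded_missing + fit$n_outcome_missing,
               nrow(d))
})

test_that("with null covariates the adjusted estimate matches the crude one", {
  cfg <- trial_config("T", n = 20000, baseline_risk = 0.15,
                      complier_rr = 0.8, compliance_rate = 1,
                      sex_rr = 1, famhist_rr = 1, flg_rr = 1,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  d <- generate_trial(cfg, 15)
  fit <- fit_binary_stage1(d)
  agg <- aggregate_from_participants(d, "eczema")
  crude <- rr_from_counts(agg$events_treat, agg$n_treat,
                          agg$events_ctrl, agg$n_ctrl)
  expect_equal(fit$effect$estimate, crude$estimate, tolerance = 0.02)
  expect_lte(fit$effect$se, crude$se * 1.01)
})

test_that("high-risk trials drop family history from the adjustment set", {
  cfg <- trial_config("T", n = 4000, high_risk_only = TRUE,
                      complier_rr = 0.8, compliance_rate = 1)
  d <- generate_trial(cfg, 16)
  fit <- fit_binary_stage1(d, high_risk_only = TRUE)
  expect_equal(fit$adjusted_for, "sex")
  expect_true(fit$converged)
})

test_that("degenerate outcomes are flagged inestimable, not estimated", {
  d <- make_trial("T", 0, 30, 0, 30)
  fit <- fit_binary_stage1(d)
  expect_false(fit$converged)
  expect_true(is.na(fit$effect$estimate))
  expect_false(fit$effect$converged)
  all_events <- make_trial("T", 30, 30, 30, 30)
  expect_false(fit_binary_stage1(all_events)$converged)
})

test_that("discrete-time cloglog fits recover a proportional-hazards truth", {
  cfg <- trial_config("T", n = 20000, baseline_risk = 0.15,
                      complier_rr = 1, compliance_rate = 1,
                      sex_rr = 1.2, famhist_rr = 1.5, flg_rr = 1,
                      tte_hazard_ratio = 0.7,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  d <- generate_trial(cfg, 18)
  fit <- fit_tte_stage1(d)
  expect_true(fit$converged)
  expect_equal(fit$effect$scale, "log_hr")
  expect_lt(abs(fit$effect$estimate - log(0.7)), 3 * fit$effect$se)

  # agreement with a continuous-time proportional-hazards oracle
  skip_if_not_installed("survival")
  tte <- derive_time_to_event(d)
  cox <- survival::coxph(survival::Surv(tte$time_days, tte$event) ~
                           d$arm + d$sex + d$family_history_atopy)
  expect_lt(abs(fit$effect$estimate - unname(stats::coef(cox)[1])),
            3 * sqrt(diag(stats::vcov(cox))[1]))
})

test_that("null hazard truth yields a null log hazard ratio", {
  cfg <- trial_config("T", n = 10000, compliance_rate = 1,
                      tte_hazard_ratio = 1,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  d <- generate_trial(cfg, 19)
  fit <- fit_tte_stage1(d)
  expect_lt(abs(fit$effect$estimate), 3 * fit$effect$se)
})

test_that("all-censored data are inestimable for the survival model", {
  d <- participant_table(trial_id = "T", participant_id = as.character(1:40),
                         arm = rep_len(c(0, 1), 40), sex = rep_len(c(0, 1), 40),
                         family_history_atopy = 0,
                         visit_ages_days = list(c(90L, 180L)))
  fit <- fit_tte_stage1(d)
  expect_false(fit$converged)
  expect_match(fit$effect$note, "no events")
})

test_that("perfect prediction in an interaction cell raises a flag, not an estimate", {
  d <- flg_perfect_prediction_trial()
  fit <- fit_interaction_stage1(d, modifier = "flg", adjust = character(0))
  expect_true(fit$perfect_prediction)
  expect_false(fit$converged)
  expect_true(is.na(fit$interaction_log_rr))
  # the offending cell is the standard-care FLG-carrier cell with 1/1 events
  cell <- fit$cells[fit$cells$treat == 0 & fit$cells$m == 1, ]
  expect_equal(cell$events, cell$n)
})

test_that("interaction estimates recover a true ratio of risk ratios", {
  cfg <- trial_config("T", n = 40000, baseline_risk = 0.12,
                      complier_rr = 0.9, compliance_rate = 1,
                      flg_prevalence = 0.3, flg_rr = 1.5,
                      flg_interaction_rr = 0.5,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  d <- generate_trial(cfg, 20)
  fit <- fit_interaction_stage1(d, modifier = "flg")
  expect_true(fit$converged)
  expect_lt(abs(fit$interaction_log_rr - log(0.5)), 3 * fit$se)

  # no interaction in truth: estimate near zero
  cfg0 <- trial_config("T", n = 40000, baseline_risk = 0.12,
                       complier_rr = 0.9, compliance_rate = 1,
                       flg_prevalence = 0.3, flg_rr = 1.5,
                       covariate_missing_rate = 0, outcome_missing_rate = 0)
  d0 <- generate_trial(cfg0, 25)
  fit0 <- fit_interaction_stage1(d0, modifier = "flg")
  expect_lt(abs(fit0$interaction_log_rr), 3 * fit0$se)
})

test_that("constant modifiers are inestimable", {
  d <- make_trial("T", 5, 30, 5, 30)
  d$flg_mutations <- 0
  fit <- fit_interaction_stage1(d, modifier = "flg")
  expect_false(fit$converged)
  expect_match(fit$effect$note, "constant")
})
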