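make_cace_trial <- function(n1c_event, n1c, n1n_event, n1n, e0, n0) {
  n1 <- n1c + n1n
  participant_table(
    trial_id = "C", participant_id = as.character(seq_len(n1 + n0)),
    arm = rep(c(1, 0), c(n1, n0)),
    adherence_days_per_week_intervention_period =
      c(rep(5, n1c), rep(1, n1n), rep(NA, n0)),
    eczema_ukwp = c(rep(c(1, 0), c(n1c_event, n1c - n1c_event)),
                    rep(c(1, 0), c(n1n_event, n1n - n1n_event)),
                    rep(c(1, 0), c(e0, n0 - e0)))
  )
}

test_that("compliance indicators follow the threshold ladder", {
  df <- participant_table(
    trial_id = "T", participant_id = as.character(1:4), arm = 1,
    adherence_days_per_week_intervention_period = c(4, 6.5, 7, NA),
    adherence_days_per_week_first3mo = c(2, 7, 5, 3)
  )
  expect_equal(build_compliance_indicator(df, compliance_spec(3)),
               c(1, 1, 1, 0))
  # the 7-days rule is equality, not >=
  expect_equal(build_compliance_indicator(df, compliance_spec(7)),
               c(0, 0, 1, 0))
  expect_equal(
    build_compliance_indicator(df, compliance_spec(5, "first_3_months")),
    c(0, 1, 1, 0))
  # sensitivity mode keeps missing adherence missing
  expect_equal(
    build_compliance_indicator(df, compliance_spec(3),
                               missing_as_noncomplier = FALSE),
    c(1, 1, 1, NA))
})

test_that("lowering the threshold never decreases the complier proportion", {
  d <- generate_trial(trial_config("T", n = 4000), 31)
  pis <- vapply(c(3, 5, 7), function(th) {
    estimate_cace_trial(d, compliance_spec(th), bootstrap_reps = 10,
                        seed = 1)$pi_complier
  }, numeric(1))
  expect_true(all(diff(pis) <= 0))
})

test_that("the moment estimator reproduces the closed-form worked example", {
  # treatment arm: 150 compliers with 15 events, 50 noncompliers with 10;
  # control arm: 35/200.  pi = .75, r1c = .10, r0c = (.175 - .25x.2)/.75
  d <- make_cace_trial(15, 150, 10, 50, 35, 200)
  res <- estimate_cace_trial(d, compliance_spec(3), bootstrap_reps = 50,
                             seed = 2)
  expect_equal(res$pi_complier, 0.75)
  expect_equal(res$risk_treat_compliers, 0.10)
  expect_equal(res$risk_ctrl_compliers_imputed, 1 / 6)
  expect_equal(exp(res$effect$estimate), 0.60)
  expect_equal(round(exp(res$itt_effect$estimate), 3), 0.714)
  expect_true(res$valid)
})

test_that("full compliance collapses the CACE onto the ITT effect", {
  d <- make_cace_trial(20, 200, 0, 0, 30, 200)
  res <- estimate_cace_trial(d, compliance_spec(3), bootstrap_reps = 50,
                             seed = 3)
  expect_equal(res$pi_complier, 1)
  expect_equal(res$effect$estimate, res$itt_effect$estimate)
})

test_that("an impossible imputed control-complier risk invalidates the trial", {
  # (1 - pi) * r1n > r0 makes r0c negative
  d <- make_cace_trial(1, 10, 9, 10, 1, 20)
  res <- estimate_cace_trial(d, compliance_spec(3), bootstrap_reps = 50,
                             seed = 4)
  expect_false(res$valid)
  expect_lte(res$risk_ctrl_compliers_imputed, 0)
  expect_false(res$effect$converged)
  expect_error(pool_cace(list(res)), "no valid")
})

test_that("bootstrap intervals are deterministic given reps and seed", {
  d <- generate_trial(trial_config("T", n = 1500, complier_rr = 0.7), 33)
  a <- estimate_cace_trial(d, bootstrap_reps = 200, seed = 7)
  b <- estimate_cace_trial(d, bootstrap_reps = 200, seed = 7)
  expect_identical(a$ci95_percentile, b$ci95_percentile)
  expect_identical(a$effect$se, b$effect$se)
  c <- estimate_cace_trial(d, bootstrap_reps = 200, seed = 8)
  expect_false(identical(a$ci95_percentile, c$ci95_percentile))
})

test_that("bootstrap CIs cover the true complier risk ratio near nominally", {
  # 200 simulated trials; nominal 95% percentile CI should cover the
  # true complier RR between 90% and 99% of the time
  theta <- 0.6
  cfg <- trial_config("T", n = 1200, complier_rr = theta,
                      compliance_rate = 0.75,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  covered <- vapply(1:200, function(i) {
    d <- generate_trial(cfg, 5000 + i)
    res <- estimate_cace_trial(d, bootstrap_reps = 200, seed = i)
    res$valid && res$ci95_percentile[1] <= theta &&
      theta <= res$ci95_percentile[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("adjusted (standardized) CACE agrees with the unadjusted one under null covariates", {
  cfg <- trial_config("T", n = 8000, complier_rr = 0.7,
                      sex_rr = 1, famhist_rr = 1, flg_rr = 1,
                      covariate_missing_rate = 0, outcome_missing_rate = 0)
  d <- generate_trial(cfg, 35)
  un <- estimate_cace_trial(d, bootstrap_reps = 100, seed = 9)
  ad <- estimate_cace_trial(d, bootstrap_reps = 100, seed = 9,
                            adjust = c("sex", "family_history_atopy"))
  expect_true(ad$effect$adjusted)
  expect_equal(ad$effect$estimate, un$effect$estimate, tolerance = 0.1)
})

test_that("pooled CACE recovers the complier effect while ITT is diluted", {
  theta <- 0.6
  cfgs <- lapply(1:3, function(i)
    trial_config(paste0("C", i), n = 6000, complier_rr = theta,
                 compliance_rate = 0.75))
  dat <- generate_scenario(scenario_config(44, cfgs))
  res <- lapply(seq_along(dat), function(i)
    estimate_cace_trial(dat[[i]], bootstrap_reps = 200, seed = 40 + i))
  pooled <- pool_cace(res)
  expect_lt(abs(pooled$pooled_estimate - log(theta)), 3 * pooled$se)
  itt <- pool_inverse_variance(do.call(rbind,
                                       lapply(res, function(r) r$itt_effect)))
  # attenuation toward the null under imperfect compliance
  expect_lt(abs(itt$pooled_estimate), abs(pooled$pooled_estimate))
})
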