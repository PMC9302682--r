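make_estimates <- function(y, se, ids = paste0("S", seq_along(y))) {
  do.call(rbind, lapply(seq_along(y), function(i) {
    effect_estimate(ids[i], "outcome", "log_rr", y[i], se[i],
                    n_total = 100L, source = "aggregate")
  }))
}

test_that("the two-study hand computation is exact", {
  p <- pool_inverse_variance(make_estimates(c(0, 2), c(1, 1)))
  expect_equal(p$Q, 2)
  expect_equal(p$df, 1)
  expect_equal(p$tau2, 1)
  expect_equal(p$I2_percent, 50)
  expect_equal(p$pooled_estimate, 1)
  expect_equal(p$se, 1)
  expect_equal(unname(p$weights), c(50, 50))
})

test_that("pooling agrees with the brute-force DL oracle on random instances", {
  set.seed(7)
  for (rep in 1:300) {
    k <- sample(2:10, 1)
    y <- stats::rnorm(k)
    se <- stats::runif(k, 0.05, 2)
    p <- pool_inverse_variance(make_estimates(y, se))
    o <- dl_pool_oracle(y, se)
    expect_equal(p$Q, o$Q, tolerance = 1e-10)
    expect_equal(p$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(p$pooled_estimate, o$random, tolerance = 1e-10)
    expect_equal(p$se, o$se_random, tolerance = 1e-10)
    expect_equal(p$I2_percent, o$I2, tolerance = 1e-10)
  }
})

test_that("pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    y <- stats::rnorm(k, 0, 0.5)
    se <- stats::runif(k, 0.1, 0.8)
    p <- pool_inverse_variance(make_estimates(y, se))
    m <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(p$pooled_estimate, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(p$se, m$se, tolerance = 1e-8)
    expect_equal(p$tau2, m$tau2, tolerance = 1e-8)
    expect_equal(p$I2_percent, m$I2, tolerance = 1e-6)
  }
})

test_that("single-study pools pass the estimate through with undefined heterogeneity", {
  e <- rr_from_counts(15, 482, 6, 494, trial_id = "A")
  p <- pool_inverse_variance(e)
  expect_equal(p$pooled_estimate, e$estimate)
  expect_equal(p$se, e$se)
  expect_equal(round(exp(p$pooled_estimate), 2), 2.56)
  expect_equal(round(p$ci95, 2), c(1.00, 6.55))
  expect_true(is.na(p$I2_percent))
  expect_equal(unname(p$weights), 100)
})

test_that("degenerate and error cases behave as documented", {
  # identical estimates: no heterogeneity at all
  p <- pool_inverse_variance(make_estimates(rep(0.4, 4), rep(0.3, 4)))
  expect_equal(p$Q, 0)
  expect_equal(p$tau2, 0)
  expect_equal(p$I2_percent, 0)
  expect_equal(p$pooled_estimate, 0.4)

  expect_error(pool_inverse_variance(make_estimates(numeric(0), numeric(0))),
               "no estimates")
  mixed <- make_estimates(c(0, 1), c(1, 1))
  mixed$scale[2] <- "smd"
  expect_error(pool_inverse_variance(mixed), "scales")
  bad <- make_estimates(c(0, 1), c(1, 1))
  bad$converged[1] <- FALSE
  expect_error(pool_inverse_variance(bad), "non-converged")
})

test_that("random-effects properties hold over random instances", {
  set.seed(23)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    y <- stats::rnorm(k)
    se <- stats::runif(k, 0.1, 1)
    ests <- make_estimates(y, se)
    pr <- pool_inverse_variance(ests, model = "random_DL")
    pf <- pool_inverse_variance(ests, model = "fixed")
    # random-effects se never smaller than fixed-effect se
    expect_gte(pr$se, pf$se - 1e-12)
    # tau2 = 0 whenever Q <= df, and then random == fixed exactly
    if (pr$Q <= pr$df) {
      expect_equal(pr$tau2, 0)
      expect_equal(pr$pooled_estimate, pf$pooled_estimate)
      expect_equal(pr$se, pf$se)
    }
    # invariance to ordering
    perm <- sample(k)
    pp <- pool_inverse_variance(ests[perm, ], model = "random_DL")
    expect_equal(pp$pooled_estimate, pr$pooled_estimate)
    expect_equal(pp$Q, pr$Q)
    # weights sum to 100
    expect_equal(sum(pr$weights), 100, tolerance = 1e-6)
  }
})

test_that("REML tau2 is available behind the flag and matches metafor", {
  skip_if_not_installed("metafor")
  set.seed(31)
  y <- stats::rnorm(6, 0, 0.6)
  se <- stats::runif(6, 0.1, 0.5)
  p <- pool_inverse_variance(make_estimates(y, se), tau2_method = "REML")
  m <- metafor::rma(yi = y, sei = se, method = "REML")
  expect_equal(p$tau2, m$tau2, tolerance = 1e-4)
  expect_equal(p$pooled_estimate, as.numeric(m$beta), tolerance = 1e-4)
})

test_that("leave-one-out locates the heterogeneity-driving trial", {
  # two near-identical trials plus one deviant: omitting the deviant
  # leaves Q ~ 0.031 < df, hence I2 = 0
  ests <- make_estimates(c(0, 0.05, 1), c(0.2, 0.2, 0.2),
                         ids = c("A", "B", "C"))
  loo <- leave_one_out(ests)
  expect_equal(loo$min_I2_trial, "C")
  expect_equal(loo$results[["C"]]$Q, 0.03125, tolerance = 1e-10)
  expect_equal(loo$results[["C"]]$I2_percent, 0)
  expect_gt(loo$results[["A"]]$I2_percent, 80)

  # homogeneous set: every omission gives I2 = 0
  hom <- make_estimates(rep(0.2, 4), rep(0.3, 4))
  expect_true(all(leave_one_out(hom)$I2_without == 0))

  expect_error(leave_one_out(ests[1, ]), "k >= 2")
})

test_that("mixed-source pooling preserves provenance and rejects duplicates", {
  ipd <- make_estimates(c(0.1, 0.2), c(0.2, 0.25), ids = c("A", "B"))
  ipd$source <- "ipd_stage1"; ipd$adjusted <- TRUE
  agg <- make_estimates(0.3, 0.3, ids = "C")

  # IPD-only input reduces to plain pooling
  p0 <- pool_mixed_sources(ipd, agg[0, ])
  expect_equal(p0$pooled_estimate,
               pool_inverse_variance(ipd)$pooled_estimate)

  p <- pool_mixed_sources(ipd, agg)
  expect_equal(p$k, 3)
  expect_equal(sum(p$weights), 100, tolerance = 1e-6)
  expect_true(p$mixed_adjustment)
  expect_setequal(p$sources, c("ipd_stage1", "aggregate"))

  agg_dup <- make_estimates(0.3, 0.3, ids = "A")
  expect_error(pool_mixed_sources(ipd, agg_dup), "both sources")
})

test_that("subgroup pools partition and recombine consistently", {
  ests <- make_estimates(c(0, 0.05, 1), c(0.2, 0.2, 0.2),
                         ids = c("A", "B", "C"))
  # two-group split reproduces hand-computed pools
  gp <- subgroup_pool(ests, c(A = "g1", B = "g1", C = "g2"))
  o <- dl_pool_oracle(c(0, 0.05), c(0.2, 0.2))
  expect_equal(gp$g1$pooled_estimate, o$random, tolerance = 1e-10)
  expect_equal(gp$g2$pooled_estimate, 1) # singleton passthrough
  expect_equal(gp$g2$k, 1)
  # all one label equals the overall pool
  all_one <- subgroup_pool(ests, c(A = "g", B = "g", C = "g"))
  expect_equal(all_one$g$pooled_estimate,
               pool_inverse_variance(ests)$pooled_estimate)
  expect_error(subgroup_pool(ests, c(A = "g", B = "g")), "unlabelled")
})
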