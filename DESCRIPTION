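Package: ipdpool
Title: Two-Stage Individual Participant Data and Aggregate Meta-Analysis
    with Compliance-Adjusted Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical machinery for comparing individual-participant-data
    (IPD) meta-analysis with traditional aggregate-data meta-analysis of
    parallel-group randomized prevention trials, modelled on infant
    skincare trials for eczema and food-allergy prevention.  Provides
    validated readers and writers for participant-level and aggregate
    trial tables with an eczema outcome hierarchy; per-trial effect
    measures (risk ratios with continuity correction, Hedges' g
    standardized mean differences, log hazard-ratio reconstruction from
    reported confidence intervals); stage-1 IPD regressions (log-binomial
    with a documented Poisson fallback, discrete-time complementary
    log-log survival models, treatment-by-covariate interactions with
    perfect-prediction detection); DerSimonian-Laird inverse-variance
    random-effects pooling with Cochran's Q, I-squared, leave-one-out
    dissection, subgroup and mixed-source pools; complier average causal
    effect (CACE) estimation under one-sided noncompliance with bootstrap
    confidence intervals; summary-of-findings arithmetic (corresponding
    risks per 1000, confidence-interval width comparison, forest tables);
    and a synthetic multi-trial cohort generator with known ground truth
    including selective serious-adverse-event reporting distortions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
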