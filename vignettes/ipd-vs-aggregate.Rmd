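---
title: "IPD versus aggregate meta-analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPD versus aggregate meta-analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ipdpool` implements the full analytical machinery needed to run a
meta-analysis of parallel-group randomized prevention trials twice —
once from published aggregate summaries and once from individual
participant data (IPD) — and to compare the two. This vignette is the
package's account of the science: the models, their assumptions, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the field's
practice is not fully standardized.

## The two analytical routes

### Aggregate route

Each trial contributes one effect estimate computed from its published
summaries.

* **Binary outcomes** — the log risk ratio
  $\hat\theta = \ln\frac{a/n_1}{c/n_0}$ with Wald standard error
  $\sqrt{1/a - 1/n_1 + 1/c - 1/n_0}$. When any of the four cells
  $a, c, n_1-a, n_0-c$ is zero, 0.5 is added to all four cells first.
  This "constant" continuity rule is the commonest meta-analytic
  convention; since the literature admits alternatives, the rule
  actually applied is recorded in each estimate's provenance `note`, so
  a sensitivity analysis can substitute another. Trials with zero
  events in both arms carry no information about a ratio and are
  flagged inestimable rather than corrected — they are excluded from
  pooling, not patched.
* **Continuous outcomes** — Hedges' $g$: Cohen's $d$ on the pooled SD,
  multiplied by $J = 1 - 3/(4N - 9)$, with variance
  $N/(n_t n_c) + g^2/(2N)$.
* **Time-to-event outcomes** — when a publication reports only
  $\mathrm{HR}\,[L, U]$, the log-scale standard error is recovered as
  $(\ln U - \ln L)/(2 \times 1.959964)$. This back-calculation assumes
  the interval was Wald-normal on the log scale, which is how such
  intervals are almost universally produced.

### Two-stage IPD route

**Stage 1** fits one regression per trial on participant-level data:

* binary outcomes: binomial GLM with **log link**, so the treatment
  coefficient is an adjusted log risk ratio — the same scale the
  aggregate route uses;
* time-to-eczema: onset is only observed at scheduled visits, so the
  natural model is **discrete-time survival**: each participant is
  expanded into one record per visit interval at risk and a binomial
  GLM with complementary log-log link of the interval event on
  treatment, covariates and an interval factor is fitted. Under
  proportional hazards in continuous time the treatment coefficient is
  the log hazard ratio, whatever the interval widths.

All stage-1 models adjust for sex, and for family history of atopic
disease except in trials that enrolled a high-risk population only
(where family history is 1 by design and the coefficient would be
inestimable). Participants missing the outcome or an included
covariate are excluded complete-case, and the counts
(`n_used`, `n_excluded_missing`, `n_outcome_missing`) always add up to
the trial size — an invariant the tests enforce.

**Stage 2** pools stage-1 estimates with exactly the same machinery as
the aggregate route, so any IPD-vs-aggregate difference is
attributable to the data, never to the pooling method.

### Pooling and heterogeneity

Inverse-variance weights $w_i = 1/se_i^2$ give the fixed-effect pool
and Cochran's $Q$; the DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right)$$

gives random-effects weights $w_i^* = 1/(se_i^2 + \hat\tau^2)$, and
$I^2 = \max(0, (Q - df)/Q) \times 100$. Design choices here, made
where the field genuinely varies:

* **DL is the default and the reporting surface** (it is what the
  standard systematic-review tooling uses); REML is available behind
  `tau2_method = "REML"` for sensitivity analyses and is cross-checked
  against `metafor` in the tests.
* **Wald-normal CIs without the Knapp–Hartung adjustment** — the
  convention under which a single-study "pool" reproduces its input CI
  exactly, which is how published single-study pooled rows are
  arithmetically consistent.
* **$k = 1$ pools are legal**: reviews routinely print single-study
  pooled rows; heterogeneity fields are `NA` there.
* $I^2$ is held at full precision internally and rounded only in
  `print` methods.

Leave-one-out dissection re-pools with each trial omitted and reports
the $I^2$-minimizing omission (ties broken by smallest $Q$) — the tool
for the "heterogeneity entirely explained by one trial" pattern.

## CACE under one-sided noncompliance

Controls cannot access the intervention, so compliance is observable
only in the treatment arm. Writing $\pi$ for the treatment-arm
complier fraction, $r_{1c}, r_{1n}$ for event risks among treatment-arm
compliers and noncompliers, and $r_0$ for the control-arm risk,
randomization plus the **exclusion restriction** (allocation affects
outcomes only through actual use, so noncomplier risk is the same in
both arms) identify the control-complier risk by the method of
moments:

$$r_{0c} = \frac{r_0 - (1-\pi)\, r_{1n}}{\pi}, \qquad
\mathrm{CACE\ RR} = r_{1c} / r_{0c}.$$

Design choices:

* **A transparent closed-form estimator with bootstrap CIs** was chosen
  over a likelihood or structural-mean formulation: every quantity in
  it is directly checkable by hand and by simulation, and its failure
  mode is explicit — when $(1-\pi) r_{1n} > r_0$ the imputed $r_{0c}$
  leaves $(0,1)$ and the result is flagged `valid = FALSE` instead of
  being reported. This is the degenerate regime that produces the
  absurdly wide intervals seen in rare-outcome CACE analyses.
* **Bootstrap**: nonparametric, resampling within arm, 2000 replicates
  by default, percentile 95% CI, `se` = SD of the log RR over valid
  replicates; invalid replicates are dropped and their fraction
  reported. Deterministic given `(reps, seed)`.
* **Covariate adjustment by direct standardization** (the moment
  estimator within covariate strata, recombined with whole-trial
  stratum weights) rather than an invented likelihood; the unadjusted
  estimator is the default reporting surface.
* Compliance definitions follow the trials' ladder — ≥3 or ≥5
  days/week, or exactly 7 days/week, over the intervention period or
  the first 3 months — and the primary definition treats missing
  adherence as noncompliance, with a sensitivity mode that keeps it
  missing.

Pooled CACE estimates the complier risk ratio; the matching ITT pool
estimates the compliance-diluted mixture effect, so under imperfect
compliance and a genuine effect the ITT estimate sits closer to the
null — an algebraic fact the tests verify numerically.

## The synthetic-cohort generator

The generator exists so that every downstream stage has data with
known ground truth. Each trial draws:

* 1:1 randomization (balanced blocks);
* binary covariates: sex (prevalence 0.5), family history of atopy
  (0.3 unless `high_risk_only`), FLG loss-of-function genotype (0.1) —
  prevalences in the range reported for general-population infant
  cohorts;
* latent complier status with probability `compliance_rate` (default
  0.75) in **both** arms, so randomization balances it;
* adherence in days/week from a normal distribution **censored** to
  $[0, 7]$, compliers centred at 5.5 (SD 1.2), noncompliers 4 days
  lower. Censoring rather than truncation is deliberate: the point
  mass at 7 is the ceiling effect of families who apply daily, and it
  is what makes the "7 days a week" (equality) compliance stratum
  non-empty. With these defaults the ≥3 days/week indicator recovers
  latent compliance with sensitivity ≈ 0.98 and specificity ≈ 0.89,
  which the tests assert as floors (0.9 / 0.8);
* eczema risk from the multiplicative model
  `baseline_risk × complier_rr^(arm·complier) × sex_rr^sex ×
  famhist_rr^famhist × flg_rr^flg` for compliers and a flat
  `noncomplier_risk` for noncompliers in both arms. The multiplicative
  form makes the stage-1 log-binomial model **correctly specified**, so
  parameter recovery is a fair test of the fitting code rather than of
  model misspecification; the built-in exclusion restriction does the
  same for the CACE estimator. Risk products above 1 are clipped, with
  a warning and a count in `attr(, "n_clipped")`;
* default baseline risk 0.15 — the 150-per-1000 assumed control risk
  used in the summary-of-findings arithmetic;
* onset visits uniform among scheduled visits for cases; or, with
  `tte_hazard_ratio` set, a discrete-time proportional-hazards process
  on the visit grid (per-interval integrated hazard $H/J$ with
  $H = -\ln(1 - \text{risk})$), which keeps the cumulative control
  risk equal to the risk model while making the log hazard ratio the
  exact truth for the cloglog stage-1 model;
* adverse events per outcome as Bernoulli with a control rate and a
  risk ratio; SAE **counts** as Poisson with
  $\lambda_0 = -\ln(1 - \text{sae\_rate})$ (so the probability of at
  least one SAE equals `sae_rate` in controls) and $\lambda_0 \times$
  `sae_rr` under intervention;
* missingness completely at random at configurable covariate and
  outcome rates (2% / 5% by default).

`published_view()` then degrades the IPD to what a publication would
show: SAEs only for participants with at least
`sae_reporting_threshold` events, and optionally eczema counts
downgraded to parent report.

Reproducibility: a master seed is mapped to per-trial substreams by a
fixed multiplicative-congruential step, so a scenario is byte-identical
under the same seed and any single trial can be regenerated alone.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: informative (non-MCAR)
missingness, cluster randomization, calendar-time enrolment,
between-visit outcome ascertainment, measurement error in adherence
beyond threshold misclassification, and correlated adverse events.
The real trials' adherence distributions are unpublished; the
generator's adherence parameters are conventional values chosen once,
not calibrations.

## Numerical conventions and edge cases

* $z_{0.975}$ is fixed at 1.959964 internally; rounding to the printed
  2-decimal precision happens only at display.
* Summary-of-findings corresponding risks use **round-half-up** to
  whole persons per 1000 (154.5 → 155), not banker's rounding; values
  above 1000 are clipped with a warning. Published tables computed
  from unrounded CI limits can disagree by one unit in the last place
  with any rule applied to the printed 2-dp ratios; the package
  defines the arithmetic from its stated inputs and leaves such
  discrepancies visible rather than special-casing them.
* CI-width comparison is on the untransformed ratio scale
  ($100 (w_b - w_a)/w_b$, positive = first interval narrower), which is
  the scale on which the published "11% narrower" figure
  back-calculates from its printed intervals; a log-scale alternative
  sits behind a flag.
* Log-binomial fitting protocol: IRLS from starting values
  (intercept = log overall event rate, slopes 0), tolerance $10^{-8}$,
  100 iterations; on failure, modified Poisson regression with an HC0
  sandwich variance, recorded in provenance (`fallback_poisson`).
  Separation is declared at coefficient magnitude ≥ 10 on the log
  scale. These thresholds are documented choices, not claims about any
  original analysis plan.
* Interaction models inspect the modifier-by-arm cells **before**
  fitting: a cell with 0% or 100% events means the interaction
  predicts the outcome perfectly, and the fit returns a
  `perfect_prediction` flag with the offending cells instead of a
  spurious coefficient.
* Eczema is resolved through the fixed hierarchy UKWP/Hanifin–Rajka >
  doctor diagnosis > parent report; the chosen level is recorded.
  Onset between visits is not modelled: a first-diagnosis visit index
  against the visit-age grid is one defensible reading of deriving
  times from "visit dates and eczema outcomes", and the convention is
  stated rather than hidden.
* Time-to-event interval expansion is per visit (not per month): the
  visit grid is the information actually available, and the cloglog
  coefficient is invariant to interval width under proportional
  hazards.

## Problem sizes used in the checks

The package's own test suite exercises: exhaustive enumeration of the
27 missing/0/1 eczema-hierarchy patterns; 1000-instance agreement of
the pooling code with an independently written brute-force
DerSimonian–Laird oracle at $10^{-10}$; stage-1 parameter recovery at
$n = 50{,}000$ within 3 standard errors; closed-form mixture
validation of the generator at $n = 50{,}000$ within 3 Monte-Carlo
SDs; pooled CACE recovery on 3 trials × 20 000 participants for
complier risk ratios 0.6 and 1.0; bootstrap CI coverage over 200
simulated trials (asserted within [90%, 99%] at nominal 95%); and the
7-trial deviant-heterogeneity and SAE-underreporting scenarios at
their documented seeds. These sizes were chosen to make Monte-Carlo
error small relative to the tolerances they are tested against.

## Known limitations

* One-stage (pooled-likelihood) IPD models, meta-regression,
  publication-bias tests, prediction intervals and network
  meta-analysis are out of scope.
* The CACE estimator assumes one-sided noncompliance and the exclusion
  restriction; it does not handle two-sided noncompliance or
  structural mean models.
* No multiple imputation: missing covariates are handled complete-case
  within each stage-1 model.
* Risk-of-bias and certainty-of-evidence judgements are qualitative
  and not computed; only their arithmetic by-products
  (summary-of-findings rows) are.
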