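---
title: "Measuring delay discounting and modelling booster willingness: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring delay discounting and modelling booster willingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boosterdd)
```

## The measurement model

### Adjusting-amount titration

The task estimates, for each of seven delays (1 week to 10 years), the
immediate amount a person treats as equivalent to $2000 delayed. It is a
binary-search staircase on the offer axis: the first offer is $1000, the
first adjustment is half the initial difference ($500), and each subsequent
adjustment halves. Choosing the delayed reward raises the next offer;
choosing the immediate reward lowers it. After `n` choices the procedure has
bisected the offer axis `n` times, so the offer that *would* be presented on
trial `n + 1` is the midpoint of the remaining interval — that offer is the
indifference-point estimate. With six trials and the default amounts the
estimate lies on a grid of width $2000/2^7 = 15.625$, and for any responder
who deterministically takes the immediate offer whenever it reaches their
subjective value, the estimate is within $15.625 of that value. The test
suite proves this by sweeping thresholds over a $1 grid on [0, 2000].

Two readings of the procedure needed a decision:

* **The hypothetical seventh trial.** We interpret it as one further
  half-step adjustment in the direction of the sixth choice — equivalently,
  the state's next-offer after six updates. This is the only reading
  consistent with the halving rule: six consecutive delayed choices give
  $1000 + 500 + \dots + 15.625 = 1984.375$, and the estimate can never
  reach the degenerate values $0 or $2000.
* **Ties.** When the offer exactly equals the responder's subjective value
  the simulated agent takes the immediate reward (certainty preference).
  Some tie rule is required for the convergence bound to hold at grid
  boundaries; which side ties fall on does not affect the bound.

Offers are kept at full numeric precision. The halving sequence produces
fractional amounts (62.5, 31.25, ...) and rounding would break the replay
identity between a trial log and its indifference point. A
`currency_precision` option exists for emulating interfaces that round.

Delay conditions are administered in ascending order by default, with an
optional seeded shuffle; the AuC is invariant to administration order, which
the tests assert.

### Area under the discounting curve

Indifference points are normalized — delay as a fraction of the longest
delay, value as a fraction of the delayed amount — anchored at (0, 1), and
integrated with the trapezoidal rule. The anchor represents the undelayed
reward at face value; without it a non-discounter would not reach AuC = 1,
so it is included in every computation here. The day-values 7, 30, 90, 180,
365, 1095, 3650 are the conventional calendar equivalents of the label set;
they are configurable, and the AuC depends on them only through the
normalized spacing. `fit_hyperbolic()` additionally recovers the rate `k`
of V = A/(1 + kD) by bounded least squares; it exists for parameter-recovery
diagnostics, while the analysis statistic is the AuC.

## Questionnaire scoring and the analytic sample

GAD-7, PHQ-9 and IUS-12 are scored as item sums after validating item counts
and ranges (0–3, 0–3, 0–5). The psychological distress index is
z(GAD-7 total) + z(PHQ-9 total), standardized with the sample mean and
standard deviation (n − 1). Since the source analysis does not state the
standardization population, we standardize within the *analytic* sample,
i.e. after exclusions; the index is exactly mean-zero there by construction.

Exclusions run in a fixed order: participants unvaccinated at follow-up are
dropped first, then participants with a missing booster response. "Prefer
not to say" on either question is treated as missing, so code-5 vaccination
responses leave with the non-responders. Counts at each step always sum to
the input n.

Gender is coded female = 1 / male = 0 and education as an ordinal 0/1/2
(secondary / undergraduate / postgraduate). The source tables report single
coefficients for both, implying scalar codings, but never state them; both
codings are configurable at the modelling interface, and the synthetic
generator uses these defaults.

## The multilevel outcome model

Booster willingness (0/1) is modelled with a logistic regression carrying
one Gaussian random intercept per country, fitted by maximizing the
marginal likelihood with `lme4::glmer` — the Laplace approximation by
default, adaptive Gauss–Hermite quadrature on request (`nAGQ`). Age,
relative income, distress and intolerance of uncertainty are z-scored
before fitting; gender, education, essential-worker status and the AuC
enter raw. An AuC odds ratio of ~2 over a (0, 1] predictor is only coherent
unscaled, which fixes this split. Fixed effects are reported as b, SE, Wald
z, two-sided p, OR = exp(b), and 95% Wald intervals exp(b ± 1.96 SE) —
Wald rather than profile intervals, matching the reporting layout the
package mirrors. Rows with a missing value in any model column are dropped
listwise.

The likelihood-ratio test compares the full model to an intercept-only
model *that retains the country random intercept*, so the test isolates the
fixed effects; the statistic is 2ΔlogLik with degrees of freedom equal to
the difference in fixed-effect counts. With the default eight predictors
the df is 8. The analysis this package re-implements prints a 7-df test
over the same eight-predictor table (and omits gender from its prose list
of predictors); we report the computed df and note the discrepancy rather
than reproduce it.

Numerical safeguards: the bobyqa optimizer with a tightened stopping
tolerance (`rhoend = 2e-9`), so that when the estimated group variance
collapses to zero the fixed effects agree with an ordinary logistic fit to
about 1e-8 (the tests require 1e-4); and a dense-integration oracle — the
per-group likelihood integrated over the random intercept with
`integrate()` at rel.tol 1e-13 — that the quadrature fit must approach
monotonically as nodes increase, matching to 1e-6 at 25 nodes on a 12-row
toy dataset.

## The synthetic cohort

The generator's defaults are the study conditions: n = 2547 participants in
13 countries (uniform weights — per-country sizes are not reported), age
Normal(30.92, 11.42) truncated at 18, relative income Normal(38.83, 23.8)
truncated to [0, 100], 22% essential workers, 55.6% female, education in
proportions 30/49/20, a random-intercept SD of 0.41, and the published
fixed effects (intercept 0.95; age 0.01; gender −0.23; education 0.02;
relative income −0.14; essential −0.08; distress 0.08; intolerance of
uncertainty −0.08; AuC 0.67).

Three generator components are not pinned down by the source and were fixed
once as follows:

* **Discount rates.** log10 k ~ Normal(−2.2, 0.6) per day, giving a median
  half-value delay of ~160 days and broad AuC spread (mean ≈ 0.20,
  sd ≈ 0.16). No distribution of k or AuC is published; these values are a
  realism choice, exposed in `cohort_spec()`, not a claim about the data.
* **Questionnaire items.** Each participant has latent severities in [0, 1]
  (Beta(2, 5), right-skewed as in community samples); every item is
  Binomial(max rating, severity). This is the simplest mechanism that spans
  the instrument range, is monotone in severity, and correlates the two
  distress instruments through the shared latent. The distress and
  uncertainty latents are given a 0.5 Gaussian-copula correlation, since
  the constructs are related; the recovery tests do not depend on the
  exact value.
* **AuC is measured, not sampled.** Each participant's AuC comes from
  running their hyperbolic agent through the titration engine, so the
  generated data inherit the task's $15.625 quantization and the
  measurement code is exercised by every cohort-level test.

What the generator deliberately does **not** emulate: panel recruitment and
attrition, choice noise in human responding (agents are deterministic given
k; a logistic-noise responder exists but is not part of the default
cohort), free-text hesitancy reasons, per-country covariate differences,
and item-level factor structure beyond a single severity dimension. Passing
recovery tests therefore show that the estimator is consistent for data
generated by this model — not that the published estimates would reproduce
on the real data, whose seeds of misfit (noise, measurement error,
confounding) are out of scope.

## Problem sizes and verification

The test suite runs the full recovery experiment at two scales, chosen as
the smallest sizes at which the checks are sharp: a single n = 20,000
cohort whose fitted odds ratios for AuC, relative income and distress must
fall inside the published 95% confidence intervals ([1.28, 2.96],
[0.78, 0.98], [1.02, 1.16]); and 50 replicates at the study's n = 2547,
whose mean coefficient estimates must sit within 3 empirical standard
errors of the generating values (a bias check with ~0.3% false-alarm rate
per coefficient). Both complete in about a minute on one core. The
remaining checks — the worked staircase example, the $1-grid convergence
sweep, AuC against an independent trapezoid, the 3185/270/368/2547
exclusion fixture, the quadrature oracle, and the scoring bounds — are
exact or near-exact and effectively instant.

## Known limitations

* The published real-data quantities that depend on the actual sample
  (χ², SEs, p-values) are not reproducible without the deposited data; the
  package covers them only through recovery experiments on calibrated
  synthetic cohorts.
* The Laplace default trades a small likelihood bias for speed; with 13
  groups of ~200 observations the bias is far below sampling error, and
  `nAGQ` raises the accuracy when groups are small.
* The staircase assumes every trial is answered; there is no partial-run
  imputation.
* `fit_hyperbolic()` assumes the hyperbolic form; it is a diagnostic, and
  model comparison between discounting forms is out of scope.
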