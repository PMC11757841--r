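# boosterdd

Delay discounting — the decline in a reward's subjective value as the delay
to its receipt grows — is a stable behavioural marker of how strongly a
person favours immediate over future payoffs. This package implements, as a
tested and reusable pipeline, a study design that asks whether shallower
discounting predicts willingness to accept a recommended COVID-19 booster
dose: an adaptive intertemporal-choice task scored by the area under the
discounting curve (AuC), questionnaire-derived covariates, and a
country-nested multilevel logistic regression, exercised end-to-end on
simulated responders and a synthetic cohort. It is aimed at behavioural and
health researchers who want to simulate, stress-test, or re-run this class
of analysis without access to participant data.

## What is implemented

**Titration task.** An adjusting-amount staircase: the participant chooses
six times per delay between an immediate amount and $2000 delayed by 1 week
to 10 years (7 delays). The first immediate offer is $1000; the first
adjustment is half the initial difference ($500) and every subsequent
adjustment halves again. Choosing the delayed reward raises the next offer,
choosing the immediate one lowers it. After six choices the indifference
point — the subjective value of the delayed $2000 — is the offer of the
hypothetical seventh trial. The estimate is always within one final
half-step ($15.625) of a deterministic responder's true value.

**AuC scoring.** Indifference points are normalized (delay as a fraction of
the maximum delay, value as a fraction of $2000), anchored at (0, 1), and
integrated by the trapezoidal rule:

AuC = Σ (x_i − x_{i−1}) · (y_i + y_{i−1}) / 2,   AuC ∈ (0, 1],

where 1 means no discounting and values near 0 mean extreme discounting.

**Scoring module.** GAD-7 (0–21), PHQ-9 (0–27) and IUS-12 (0–60) item-sum
totals with validation; a psychological distress index z(GAD-7) + z(PHQ-9);
vaccination/booster response coding; the analytic-sample exclusion pipeline
(unvaccinated first, then missing booster responses); and percent agreement
/ Cohen's kappa for inter-rater reliability tables.

**Inference.** `fit_booster_glmm()` fits
logit P(willing) = Xβ + u_country, u ~ N(0, σ²), via `lme4::glmer`
(Laplace or adaptive Gauss–Hermite), reporting b, SE, Wald z, p, OR = exp(b)
and 95% CIs exp(b ± 1.96·SE), plus the random-intercept variance, a
likelihood-ratio test against the intercept-only model, and group
discounting curves by outcome.

**Synthetic cohort.** `generate_cohort()` draws covariates from the study's
reported marginals, measures each participant's AuC by running a hyperbolic
agent (V = A/(1 + kD), log10 k ~ Normal(−2.2, 0.6)) through the actual
titration engine, and draws booster outcomes from the multilevel model with
the published coefficients — so the estimator can be checked by parameter
recovery.

## Worked example

```r
library(boosterdd)

cfg <- task_config()                       # $1000 now vs $2000 later, 6 trials
s <- titration_start(cfg, "3 years")       # offer $1000, step $500
s <- titration_choose(s, "delayed")        # next offer $1500
s <- titration_choose(s, "immediate")      # next offer $1250

p <- run_task(responder("hyperbolic", k = 0.01), cfg)
p
#> Discounting profile: 7 indifference points, delayed amount 2000
#>     label days subjective_value
#>    1 week    7         1859.375
#>   1 month   30         1546.875
#>  3 months   90         1046.875
#>  6 months  180          703.125
#>    1 year  365          421.875
#>   3 years 1095          171.875
#>  10 years 3650           46.875
#> AuC = 0.1109
```

An agent discounting at k = 0.01/day values $2000 at half after 100 days;
its titrated indifference points track A/(1 + kD) to within the task's
$15.625 resolution, and the AuC of 0.11 marks a steep discounter.

The full analysis — simulate agents, generate and score the cohort, fit the
model, summarize group curves — is the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_simulate_task.R
Rscript analysis/02_generate_cohort.R
Rscript analysis/03_score.R
Rscript analysis/04_fit_model.R
Rscript analysis/05_group_curves.R
```

Each writes its tables under `results/`. On the default synthetic cohort
(n = 2547, 13 countries) the fitted model reports, e.g., an AuC odds ratio
near 2 with a positive LRT against the intercept-only model, mirroring the
structure of the published Table the generator is calibrated to.

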