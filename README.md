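# wqsmix

Weighted quantile sum (WQS) regression for correlated environmental
exposure mixtures, with binary and discrete-time survival outcomes.

## The problem

Ambient fine particulate matter (PM₂.₅) is a mixture: sulfate, nitrate,
ammonium, carbon fractions and trace metals co-vary strongly across
space, so single-pollutant regressions cannot say *which* constituents
drive an observed health association. WQS regression addresses this by
estimating one **mixture index** with non-negative constituent weights,
interpretable as each constituent's relative importance. The package
was built for cohort studies of kidney-transplant recipients — where
outcomes include delayed graft function (DGF), first-year acute
rejection, death-censored graft failure and all-cause mortality — but
the machinery is generic: any area-level annual exposure panel, any
binary or time-to-event outcome.

## The model

Each exposure is scored into deciles, `d_i ∈ {0, …, 9}`, with cut
points computed once on the full analysis sample. Stage 1 estimates
weights `w_i ≥ 0, Σ w_i = 1` on a training split by maximizing the
logistic likelihood of

    logit P(Y = 1) = β₀ + β₁ Σᵢ wᵢ dᵢ + γ′Z

over `B = 100` bootstrap resamples; the averaged weights are frozen.
Stage 2 regresses the outcome on the index `wqs = Σ wᵢ dᵢ` in the
held-out validation split, reporting the effect per one-decile increase
in the whole mixture as an adjusted odds ratio, or — for time-to-event
outcomes — as an adjusted hazard ratio from pooled logistic regression
on person-month records,

    logit P(Y_t = 1 | Y_{t-1} = 0) = β₀ + β₁ wqs + γ′Z + βₜ′S(t),

with a natural cubic spline `S(t)` for the baseline hazard, the
standard discrete-time approximation to a Cox model when monthly risks
are small. Individual exposure is linked from an annual area panel by
the calendar-weighted one-year pre-transplant moving average: a
transplant in month *m* of year *y* weights year *y* by *m*/12 and year
*y−1* by (12−*m*)/12 (July → 7/12 and 5/12).

The simplex constraint is solved exactly on the product scale
`c_i = β₁ w_i`, where each sign branch is a convex box-constrained
logistic MLE (L-BFGS-B with analytic gradients), so corner solutions
with `w_i = 0` are attained exactly.

## Worked example

Simulate a cohort with known ground truth (true weights Ni 0.5,
Pb 0.3, Zn 0.2; true per-decile OR 1.2) and fit the full two-stage
model:

```r
library(wqsmix)
cfg <- sim_config(n_recipients = 3000, seed = 42)
sim <- simulate_wqs_cohort(cfg)
dat <- wqs_analysis_table(sim)
fit <- wqs(dgf ~ age + sex + donor_deceased + cit + deprivation,
           data = dat, mixture = cfg$constituents, B = 100, seed = 42)
print(fit)
#> Weighted quantile sum regression (binomial)
#>   n = 3000 (1200 train / 1800 validation), 10-quantile scores
#>   stage-1 bootstraps used: 100 of 100
#>   aOR per 1-decile increase in the mixture: 1.2167 (95% CI 1.1505-1.2867)
#>   percent increase: 21.7% (95% CI 15.0%-28.7%)
#>   top constituent weights: Ni 31.4%, Zn 17.2%, Pb 13.0%
head(weight_table(fit), 3)
#>   constituent    weight importance_pct
#> 1          Ni 0.3141906           31.4
#> 2          Zn 0.1718635           17.2
#> 3          Pb 0.1299518           13.0
```

The validation-set confidence interval covers the generating odds ratio
1.2, and the three constituents carrying the true signal rank first —
with the expected shrinkage of individual weights toward uniform that
bootstrap-averaged WQS weights show at moderate sample size.
Time-to-event outcomes use the same interface with a `Surv()` left-hand
side:

```r
fit_gf <- wqs(survival::Surv(months_graft, event_graft) ~ age + sex,
              data = dat, mixture = cfg$constituents, B = 100, seed = 42)
```

`wqs_interaction(fit, "sex")` adds an effect-measure-modification term
and reports subgroup estimates with a Wald interaction P value;
`run_wqs_pipeline()` chains every stage (simulate/link → deciles →
split → bootstrap weights → stage-2 fits → interactions → sensitivity
truncation) and writes CSV/JSON reports with a provenance manifest.

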