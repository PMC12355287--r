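---
title: "Methods: weighted quantile sum regression for constituent mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted quantile sum regression for constituent mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqsmix)
```

## Scope

`wqsmix` estimates the joint association of a correlated mixture of
airborne particulate constituents with post-transplant health outcomes.
Its parts are: (1) calendar-weighted linkage of an annual, area-level
exposure panel to individuals; (2) two-stage weighted quantile sum
(WQS) regression with bootstrap-estimated, simplex-constrained
constituent weights; (3) pooled logistic regression on person-month
records for time-to-event outcomes; (4) interaction-based
effect-measure-modification fits; and (5) a synthetic-cohort generator
with known ground truth used to validate all of the above.

## Exposure linkage

The exposure of record is the moving average of each constituent over
the twelve months preceding transplantation. Only annual means are
available per zip code, so a transplant in month $m$ of year $y$ is
assigned $({m}/{12})\,x_{y} + ({(12-m)}/{12})\,x_{y-1}$ per
constituent. The convention that the transplant month counts fully
toward the transplant year is the only one consistent with a July
transplant weighting the two years 7/12 and 5/12; it implies a January
transplant still takes 1/12 from the transplant year, which we document
rather than assert as uniquely correct. Area identifiers are opaque
strings (leading zeros preserved); missing panel rows are never
interpolated — affected recipients are dropped with a logged count, or
abort the run under `policy = "strict"`.

## Quantile scoring

Each constituent is scored into $q = 10$ empirical decile bins,
$d_i \in \{0, \dots, 9\}$, so a coefficient is "per one-decile
increase". Cut points are computed once on the full analysis sample,
*before* splitting, so a given score means the same concentration range
in the training and validation halves; this is a design choice, exposed
through the `cuts` argument. Bins are right-closed on the cut points
(ties go to the lower bin), matching the empirical-CDF convention and
making scores invariant to any strictly increasing transform of the
data. A constituent with no variation gets all-zero scores and a
warning rather than an error, so degenerate columns are visible but not
fatal.

## Stage 1: constrained weight estimation

Stage 1 maximizes the Bernoulli likelihood of
$\operatorname{logit} P(Y=1) = \beta_0 + \beta_1 \sum_i w_i d_i +
\gamma'Z$ over simplex-constrained weights and unconstrained
coefficients. We solve it on the product scale $c_i = \beta_1 w_i$:
the constraint set is exactly $\{c \ge 0\} \cup \{c \le 0\}$, and each
sign branch is a *convex* box-constrained logistic maximum-likelihood
problem. Each branch is solved with L-BFGS-B, analytic gradients, and
internally standardized covariates (coefficients are mapped back on
exit); the better branch wins, with $w = c/\sum_i c_i$ and
$\beta_1 = \sum_i c_i$. Corner solutions — weights exactly zero — are
attained exactly by the active-set method, which a smooth simplex
reparameterization (softmax) cannot do: in development, softmax
iterates stalled within about $10^{-3}$ log-likelihood units of
boundary optima, detectable against an exhaustive 0.02-resolution
simplex grid search; the convex formulation attains the grid bound to
$10^{-6}$ (see `test-acceptance.R`). Because each branch is convex,
random restarts are kept only as a fallback on convergence failure.
When $\beta_1 = 0$ the weights are unidentified; a uniform vector is
returned with the (still maximal) likelihood.

Weights are estimated on `B = 100` subject-level bootstrap resamples of
the training split (clustered by recipient for person-period data, so
a resampled subject contributes all their months) and averaged without
signal-strength weighting — the plain mean — then renormalized; the
count of converged resamples is reported. Stage-1 fits adjust for the
same covariates (and, for survival outcomes, the same spline-in-time
columns) as stage 2; `stage1_adjust = FALSE` turns this off.

## Stage 2: validation-split inference

With stage-1 weights frozen, the mixture index
$wqs = \sum_i w_i d_i \in [0, 9]$ is computed for validation
recipients and the outcome is regressed on $(wqs, Z)$ by ordinary
logistic regression. We report $\beta_1$, its Wald 95% interval, and
$(\exp(\beta_1)-1)\times 100$ — the percent increase in the odds (or
discrete-time hazard) per one-decile increase in every constituent
jointly — with interval endpoints transformed identically. Wald
intervals are used because the split already isolates inference from
weight estimation; no bootstrap interval is attempted. The default
split is 40% training / 60% validation — the convention of the WQS
literature — and is exposed as `train_fraction`; the split is a simple
random partition driven by one master seed that fans out
deterministically to the split, bootstrap and restart streams.

Supplying `fixed_weights` skips stage 1 entirely and fits stage 2 on
the full sample: the intended uses are applying externally published
weights to a new cohort and simulation studies with known truth.

## Discrete-time survival

Follow-up of $T$ months becomes $T$ person-month rows, with the event
indicator 1 only in the final row of an event; a subject censored at
24 months contributes exactly 24 event-free rows. Month indexing
starts at $t = 1$, administrative censoring is at 60 months, and an
event recorded beyond the horizon becomes a censoring at the horizon
(logged). Same-month event and censoring resolves to the event. The
pooled logistic model adds a natural cubic spline in $t$ (default
`spline_df = 4`, a standard flexible-baseline choice; configurable)
with interior knots at equally spaced quantiles of observed *event*
times and boundary knots at the observed range, linear beyond. The
model is fit on the event indicator, so the reported
$\mathrm{aHR} = \exp(\beta_1) > 1$ means increased hazard; this is the
sign-flipped but otherwise identical parameterization of the
conditional-survival form of the model. Censoring is assumed
non-informative; no inverse-probability-of-censoring machinery is
included. Variance comes from the pooled fit and ignores
within-recipient correlation of person-months — with at most one event
per subject and rare monthly risks this is the usual practice, but it
is a known limitation. Death-censored graft failure is handled in data
construction: a subject dying event-free is censored at the death
month. `truncate_followup()` (or `horizon = 12`) restricts to the
first post-transplant year as a sensitivity analysis; extra adjustment
covariates (e.g. copollutants) enter through the model formula.

## Effect-measure modification

`wqs_interaction()` refits stage 2 with a binary modifier's main
effect and its product with $wqs$, keeping stage-1 weights frozen —
interactions enter stage 2 only, so the constituent ranking is common
to all subgroups. The reference-level effect is $\exp(\beta_1)$, the
modifier-level effect $\exp(\beta_1 + \beta_{int})$ with its interval
from the coefficient covariance, and the Wald test on $\beta_{int}$
gives the interaction P value. Age and cold ischemia time enter the
pipeline as the clinical dichotomies (≥55 years, >12 hours). No
multiplicity correction is applied across modifiers and outcomes; this
mirrors common practice and is deliberately left to the analyst.

## The synthetic generator

`simulate_wqs_cohort()` draws: a two-year zip-level panel of 15
constituents from a Gaussian copula with lognormal marginals whose
medians and IQRs match typical US zip-code-level values (units:
µg/m³ for EC, NH₄⁺, NO₃, OC, SO₄²⁻; ng/m³ for the trace elements);
exchangeable correlation 0.5 with a 0.85 block among the
secondary-aerosol species (SO₄²⁻, NO₃, NH₄⁺, OC), emulating their
shared chemistry; recipients assigned to zips by a skewed multinomial
(urban clustering), with age, sex, donor type, cold ischemia time and
an area-deprivation score as covariates; binary outcomes from a
logistic model on the true weighted decile index (DGF-like baseline
prevalence 18.6%, rejection-like 8.4%); and survival outcomes by
month-by-month Bernoulli draws with logit-hazard
$\alpha(t) + \beta_1\,wqs + \gamma'Z$, independent monthly censoring,
and administrative censoring at 60 months. Default true weights are
Ni 0.5, Pb 0.3, Zn 0.2 with per-decile OR 1.2 (binary) and per-decile
hazard ratios 1.047 (graft failure) and 1.039 (death). The signal sits
on trace elements *outside* the high-correlation block deliberately:
weights inside an 0.85-correlated block are not individually
identifiable at any realistic sample size, and a generator whose
ground truth cannot in principle be recovered cannot validate the
pipeline. An optional `confounding` parameter links the deprivation
covariate to zip-level log sulfate; it defaults to 0 because the real
confounding structure is unknowable, and it exists so users can probe
sensitivity.

What the generator does **not** emulate: spatially structured exposure
surfaces (zips are exchangeable draws), exposure measurement error
from aggregation, residential mobility, informative censoring,
time-varying exposure, and the registry's covariate richness. Passing
tests on synthetic data therefore demonstrate the statistical
machinery — not robustness to these real-data features.

## Identifiability of individual weights

A point worth stating prominently: in the stage-1 GLM the information
about $c_i = \beta_1 w_i$ scales like
$n\,p(1-p)\,\mathrm{Var}_{partial}(d_i)$, so with $n_{train} = 2000$,
prevalence ~0.19 and $\beta_1 = \ln 1.2$, the sampling standard
deviation of each *weight* is roughly 0.1 even for independent
constituents, and the non-negativity constraint spreads a substantial
positive-part mass (~0.03–0.05 each) over the null constituents,
deflating large signal weights toward uniform. At this scale WQS
reliably recovers the *ranking* and the joint signal mass, but not
individual weights to tight tolerances; tight weight recovery needs
tens of thousands of training subjects (registry scale). The test
suite asserts the ranking/concentration property at desk scale and
retains a strict fixed-tolerance recovery check at its stated
conditions in the acceptance file, where its failure documents exactly
this sampling floor.

## Numerical and testing choices

Objective tolerance $10^{-8}$ (L-BFGS-B `factr` scaled accordingly);
weight sums enforced to 1 within $10^{-8}$; decile ties to the lower
bin; degenerate constituents scored zero with a warning; manifest
timestamps are opt-in so identical configuration and seed reproduce
byte-identical results bundles. Problem sizes in the test suite are
the package's own desk-scale choices: simplex battery over 1000 small
fits; grid-oracle comparison on 20 datasets of $n = 300$, $J = 3$;
Wald coverage over 200 replicates at $n = 3000$; Cox-approximation
bias over 100 replicates at $n = 4000$ with monthly hazard below 1%;
interaction calibration over 200 null replicates with a
Kolmogorov–Smirnov uniformity check and subgroup recovery over 100
replicates at $n = 6000$.
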