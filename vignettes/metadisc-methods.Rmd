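---
title: "Models and methods in metadisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in metadisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadisc)
```

`metadisc` chains two statistical layers: a behavioral layer
(hyperbolic discounting of delayed, risky, or effortful monetary
rewards, fit to trial-level choices) and a meta-analytic layer
(published correlations between PET measures of striatal dopamine
function and discounting indices, harmonized and modeled jointly).
This vignette explains the models, the conventions and tunable
parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Harmonizing published effects

A published effect arrives as a correlation `r` (Pearson, partial, or
Spearman treated as Pearson) or as a t statistic with degrees of
freedom, from which `r = sign(t) sqrt(t^2/(t^2 + df))`. Correlations
are bounded and skewed, so modeling happens on the Fisher scale,
`z = atanh(r)`, with the large-sample standard error `1/sqrt(n - 3)`.

Two conventions deserve emphasis:

- **Sign alignment.** Discounting indices disagree on direction: the
  discount rate `k`, `ln k`, and the proportion of smaller-cost
  choices rise with steeper discounting, while area-under-the-curve
  and the proportion of larger/high-effort choices fall, and a drug
  occupancy measure is inversely related to the underlying binding
  potential. `sign_align()` flips z for the second set, so a positive
  harmonized z always reads "more of the dopamine measure, steeper
  discounting". Flipping twice is the identity, which the tests
  exercise.
- **Partial correlations** from covariate-adjusted analyses keep the
  plain `1/sqrt(n - 3)` standard error, with no degrees-of-freedom
  penalty for the covariates. This matches the convention of the
  summary tables the bundled fixture transcribes (e.g. SE = 0.097 for
  a partial correlation with n = 109), and for the small covariate
  counts involved the difference is well under the printed precision.

Sub-condition correlations reported within one task are pooled by
averaging their z values — an approximation to the full-task
correlation that ignores the correlation between sub-conditions, kept
because the originating analyses provide no within-task covariance.

Effects from the same sample (e.g. a baseline-binding and a
drug-release measure in the same twelve subjects) enter as independent
rows. This replicates the original single-level model and is a known
limitation: it understates the uncertainty of groups contributing
correlated rows. A study reporting only a quadratic association cannot
contribute a linear effect and is excluded at ingest via an explicit
`exclude` flag — loading messages name the dropped rows, never
silently. If both `r` and `(t, df)` are present, `r` wins with a
warning. Region labels are stored but never re-selected: choosing the
region with the largest effect within a study is a judgment made when
the table is assembled, not by the loader.

## The random-effects meta-regression

Harmonized effects follow

$$z_i \sim N(x_i'\beta,\; se_i^2 + \tau^2),$$

where $x_i$ dummy-codes the moderators with *healthy* and *D2
receptor* as reference levels, and $\tau^2 \ge 0$ is the
between-effect variance. Four named structures are built in:
`intercept` (common correlation), `group`, `tracer`, and
`group_x_tracer`.

**Estimation.** $\tau^2$ maximizes the restricted log-likelihood,
profiled so the search is one-dimensional; $\beta$ is the weighted
least-squares solution at the optimum with weights
$1/(se_i^2 + \hat\tau^2)$. The restricted likelihood includes all its
constants plus the $\tfrac12\log|X'X|$ term, so
$\mathrm{AIC} = -2\ell_{REML} + 2(p + 1)$ — counting $\tau^2$ as a
parameter — is on the conventional scale and matches the reference
meta-analysis implementation to numerical precision (the test suite
asserts agreement with `metafor` at `1e-6`). Because restricted
likelihoods of models with different fixed effects are not strictly
comparable, `compare_models()` ranks by AIC but attaches a warning
saying exactly that.

**Numerics.** The profile is maximized by Brent search on
$[0, \max(100\,\mathrm{max}(se^2),\,10\,\mathrm{var}(z),\,1)]$,
followed by a second Brent pass in a `1e-4`-wide bracket around the
coarse optimum (Brent's absolute accuracy on a wide interval is
limited by its relative tolerance; the polish brings $\hat\tau^2$
within `1e-6` of a dense grid-search oracle, which the tests verify).
The boundary value $\tau^2 = 0$ is always compared against the
interior candidate. With as many coefficients as effects the model is
saturated and $\tau^2$ is fixed at 0; with fewer than $p + 2$ effects
a warning marks $\tau^2$ as unidentifiable.

**Heterogeneity.** QE is Cochran's Q of the inverse-variance
fixed-effect fit (weights $1/se_i^2$); QM is the joint Wald statistic
of the non-intercept coefficients (of the intercept, for the
intercept-only model). $I^2 = 100\,\tau^2/(\tau^2 + s^2)$ uses the
generalized typical within-effect variance
$s^2 = (k - p)/\mathrm{tr}(P)$ computed from the trace of the
inverse-variance hat matrix, so the definition carries over to
moderated models unchanged.

**Inference.** Wald (normal) tests and confidence intervals
throughout, with the 95% multiplier fixed at 1.959964; group
predictions $x_g'\hat\beta$ and their interval endpoints are mapped to
the correlation scale through `tanh`, which keeps them inside
$(-1, 1)$ and preserves ordering.

**Rank deficiency.** The group-by-tracer interaction has empty cells
in realistic tables (addiction samples measured only D2 receptors;
the transporter appears only in one group), so non-estimable columns
are dropped with a message and recorded in `$dropped` rather than
erroring — the coefficients that remain are the estimable ones, and
reports surface the dropped names. A design that loses its *intended*
test column (e.g. the precision column of the Egger test when all
standard errors are equal) is an error instead.

## Publication-bias diagnostics

`egger_test()` enters each effect's standard error as an additional
fixed-effect moderator of the same REML model and reports the Wald Z
of that coefficient. This "precision as moderator" variant — rather
than the classical weighted regression of $z/se$ on $1/se$ — is the
appropriate form when the asymmetry question is posed on a moderated
random-effects model, and the same variant is applied uniformly to
every model structure. The test statistic is invariant to shifting all
effects by a constant whenever the design contains an intercept (a
property test covers this), and its type-I error under a simulated
null stays near nominal.

`funnel_data()` pairs each effect's residual $z_i - x_i'\hat\beta$
with its standard error; pseudo-confidence regions at two-sided levels
0.90/0.95/0.99 have half-width $z_{crit}\sqrt{se^2 + \hat\tau^2}$,
mirroring the conventional p-value bands (0.10, 0.05, 0.01) of
published funnel displays. At the fitted coefficients the
precision-weighted mean residual is zero by construction.

## The behavioral model

Each trial offers a smaller reward at a smaller cost against a larger
reward at a larger cost. Subjective value is hyperbolic,
$SV = R/(1 + kC)$, with the cost transform per domain: delay in days
for time (a month is counted as 30 days, a week as 7), odds against
winning $(1 - p)/p$ for probability (a certain reward has zero cost; a
zero win probability is rejected as an infinite cost), and the
proportion of maximum button-press rate for effort. Choice follows a
single-parameter softmax,
$P(\text{smaller}) = \mathrm{logistic}(\beta_s (SV_s - SV_l))$ — one
inverse temperature on the SV difference, the minimal rule consistent
with the task descriptions. Because fitted `k` values are heavily
skewed, the reported transform is `Ln(k + 1)` alongside raw `k` and
the model-free proportion of smaller-cost choices.

**Fitting** is per subject (the summaries of interest are per-subject
rates): deterministic multistart maximum likelihood, L-BFGS-B from a
fixed 8×8 log-spaced grid of starts inside the box $k \in [0, 5]$ (on
the transformed-cost scale), $slope \in [0, 50]$. No stochastic
optimizer is involved, so a dataset always yields the same fit. The
log-likelihood uses `plogis(·, log.p = TRUE)` for numerical stability.
Three degeneracies are flagged rather than hidden: solutions on the
box edge, one-sided datasets (every choice identical), and flat
likelihoods — a fit that fails to beat the random responder
(all probabilities 0.5) by a 2-df likelihood-ratio margin is marked
`flat_likelihood`, since `(k, slope)` are then not jointly
identifiable. Trials whose transformed costs are equal (only possible
through misconfiguration) are rejected at validation.

## Synthetic data: what it emulates, and what it does not

`task_grid()` reproduces the factorial cost structures of the three
tasks: time offers today/2 weeks/1 month against 2 weeks/1 month/6
weeks (84 trials, young-adult variant) or today/2/4 months against
2/4/6 months (82 trials); probability offers win probabilities
0.50/0.75/1.00 against options 0.25 or 0.50 lower; effort offers
35/55/75% of maximum press rate against 20 or 40 points more. The
smaller reward is drawn 1–50% below the larger one. The magnitude of
the larger reward is drawn uniformly on 10–50 currency units — the
task descriptions fix only the relative discount range, so the base
magnitude is a package choice, configurable on the grid.
`generate_choice_dataset()` samples cost pairs uniformly, draws
choices from the softmax model, and is deterministic given a seed
(restoring the global RNG state afterwards).

`generate_effect_collection()` draws per-effect sample sizes, group
labels (by proportion or fixed counts), true effects
$\beta_{group} + N(0, \tau^2)$ and observed effects with sampling
noise $N(0, 1/(n-3))$ — exactly the meta-regression's assumed data
model. A generated collection's observed variance decomposes into
$\tau^2 + 1/(n-3)$, which a 5000-effect property test verifies.

What the generators deliberately do **not** emulate: within-study
correlation between effects from the same sample, non-normal true
effect distributions, selective reporting (funnel asymmetry), real
response lapses or trial-order effects, and any PET measurement model.
Passing recovery tests therefore show that the estimators invert the
package's own data model at realistic sizes — not that real choice
data or real literatures satisfy that model.

## Simulation sizes and honest caveats

The validation experiments use fixed sizes chosen to estimate the
properties they test with useful precision: 200 simulated subjects per
domain for discounting recovery (82-trial grids, k log-uniform over
per-domain plausible ranges — time 5e-4–0.25, probability 0.1–3,
effort 0.05–2, anchored to the typical fitted `Ln(k+1)` magnitudes of
the respective tasks — with the softmax slope fixed mid-range at 0.5),
500 replicate collections of 50 effects for meta-regression recovery,
and 1000 replicates of 30 effects for the asymmetry test's type-I
error.

Three caveats are worth stating plainly:

- The expected proportion of smaller-cost choices is *not* globally
  monotone in the true rate: on trials where both options carry
  nonzero cost, both subjective values collapse toward zero as `k`
  grows and the choice drifts back toward indifference (on the
  82-trial lifespan time grid the expected share peaks near k = 0.03).
  Monotonicity holds — and is tested — on the range real subjects
  occupy.
- The effort task has limited resolving power at low rates: its
  transformed costs span only 0.35–0.95, so for `k` below roughly 0.2
  the likelihood barely distinguishes candidates and maximum-likelihood
  ties at `k = 0` occur, which depresses rank-correlation recovery for
  that domain relative to time and probability. This mirrors the floor
  effects reported for finger-press effort paradigms.
- Monte-Carlo acceptance checks phrased as "within 3 simulation
  standard errors" are stochastic by construction, with a roughly 1%
  false-alarm probability per comparison at any fixed seed.

## Limitations

Beyond the independence assumption for same-sample effects and the
synthetic-data simplifications above: no multilevel or robust-variance
meta-analysis, no trim-and-fill or selection models, no
Knapp–Hartung small-sample adjustment (Wald inference matches the
reproduced analyses), and no alternative discount functions
(exponential, quasi-hyperbolic) — the hyperbolic form is the modeled
contribution, and the code structure leaves other forms as an
extension point rather than an option.
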