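# metadisc

Dopamine PET effect sizes and reward discounting: effect-size
harmonization, random-effects meta-regression, publication-bias
diagnostics, and the underlying hyperbolic discounting choice model.

## The problem

A recurring question in decision neuroscience is whether trait-like
individual differences in striatal dopamine function — D2-like receptor
availability (BP_ND), dopamine synthesis capacity, or transporter
availability measured with PET — track how steeply people discount
rewards by delay, uncertainty, or physical effort. The published
evidence is heterogeneous: studies report Pearson or partial
correlations, t statistics, Spearman coefficients, or sub-condition
correlations, computed on discounting indices that point in opposite
directions (a discount rate *k* rises with discounting; an
area-under-the-curve measure falls). `metadisc` is for researchers who
want to place such effects on one common scale, model them jointly with
clinical-group and radiotracer moderators, and interrogate the result
for heterogeneity and small-study bias — and for anyone fitting the
behavioral model those effects are built on.

## The models

**Harmonization.** Each published effect is converted to a signed
Fisher-z value and standard error:

- from a t statistic: `r = sign(t) * sqrt(t^2 / (t^2 + df))`
- Fisher transform: `z = atanh(r)`, with `SE = 1 / sqrt(n - 3)`
- sign alignment: z is flipped for indices that *decrease* with
  discounting (AUC, proportion of larger/high-effort choices, or a drug
  occupancy correlate inversely related to binding), so that positive z
  always means "more of the dopamine measure, steeper discounting"
- sub-condition correlations are pooled by averaging their z values;
  partial correlations from covariate-adjusted analyses use the same
  `1/sqrt(n - 3)` standard error.

**Meta-regression.** Harmonized effects follow a random-effects model

    z_i ~ Normal(x_i' beta, se_i^2 + tau^2)

with the between-effect variance tau^2 estimated by restricted maximum
likelihood (profiled Brent search) and dummy-coded moderators for
clinical group (healthy reference) and tracer target (D2 receptor
reference). The fit reports Wald tests, Cochran's Q statistics (QM for
the moderators, QE for residual heterogeneity), I^2 (with the
hat-matrix typical-variance convention so it extends to moderated
models), the restricted log-likelihood, and AIC = -2 logLik + 2 (p+1).
Group-level predictions are mapped back to correlations through tanh.
An Egger-type asymmetry test enters each effect's standard error as an
additional REML moderator; funnel data pair residuals with precision.

**Behavior.** Trial-level choices between a smaller-cost and a
larger-cost monetary reward are modeled with a hyperbolic subjective
value `SV = R / (1 + kC)` — where C is the delay in days, the odds
against winning `(1 - p)/p`, or the proportion of maximum press rate —
and a softmax choice rule `P(smaller) = logistic(slope * (SV_s -
SV_l))`, fit per subject by deterministic multistart maximum
likelihood. Both `Ln(k + 1)` and the model-free proportion of
smaller-cost choices are reported.

## Worked example

```r
library(metadisc)

tab <- table1_effects()        # bundled: 14 harmonized time-discounting
fit <- reml_meta(tab, ~ group) # effects from 7 PET studies
summary(fit)
```

```
Random-effects meta-regression (REML)
  moderators: ~group
  k = 14 effects, p = 3 fixed-effect coefficients

                           estimate     se       z      p   ci_lo   ci_hi
(Intercept)                 -0.1383 0.1096 -1.2619 0.2070 -0.3530  0.0765
groupaddiction              -0.6160 0.2019 -3.0514 0.0023 -1.0117 -0.2203
groupother_psychopathology   0.7934 0.1988  3.9915 0.0001  0.4038  1.1830

  tau^2 = 0.0274 (between-effect variance, z^2 units)
  I^2   = 31.76%
  QE (residual heterogeneity) = 16.296, df = 11, p = 0.1305
  QM (omnibus moderators)     = 35.728, df = 2, p = 1.745e-08
  logLik (REML) = -3.1314, AIC = 14.2629
```

Healthy samples show essentially no pooled association between the
dopamine measure and time discounting (intercept −0.138, n.s.), while
addiction samples sit 0.616 z units lower (stronger negative
correlations) and other psychopathology (Parkinson's disease, obesity,
ADHD) 0.793 z units higher. On the correlation scale:

```r
predict_group(fit)
```

```
                  group          z  ...          r       r_lo        r_hi
1               healthy -0.1382517  ... -0.1373776 -0.3390246  0.07633784
2             addiction -0.7542553  ... -0.6376807 -0.7956268 -0.39855481
3 other_psychopathology  0.6551336  ...  0.5751157  0.3185957  0.75314545
```

```r
egger_test(tab, ~ group)
```

```
Egger-type test for small-study asymmetry (SE as REML moderator)
  base moderators: ~group   (k = 14 effects)
  slope = -1.640 (SE 0.731), Z = -2.243, p = 0.0249
```

The negative precision slope (Z = −2.24, p = 0.025) flags funnel
asymmetry: less precise studies tend to report more negative harmonized
effects. And the behavioral model on a simulated subject:

```r
d <- generate_choice_dataset(task_grid("time"), k = 0.01, slope = 0.5,
                             seed = 42)
fit_discount(d)
```

```
Hyperbolic discounting fit (time domain, subject sim01, 82 trials)
  k = 0.008751  (Ln(k+1) = 0.008713),  softmax slope = 0.6965
  logLik = -20.4563,  proportion smaller-cost choices = 0.817
```

The generating rate k = 0.01 is recovered as 0.0088 from 82 trials.

## Command line

A thin CLI over the same functions ships in `inst/cli/metadisc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","metadisc.R",package="metadisc"))')" \
    repro --models intercept,group --out-dir repro_out
```

Subcommands: `harmonize`, `meta`, `bias`, `fit-discounting`,
`simulate`, `repro`. `repro` writes per-model coefficient CSVs, funnel
data, a model-comparison table, a JSON report, and a side-by-side table
of computed vs published values (`run_reproduction()` does the same
from R).

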