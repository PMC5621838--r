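# funnelbias

Publication-bias assessment for meta-analyses of continuous outcomes — and a
simulation engine showing when the standard workflow produces false alarms.

## The problem

Meta-analysts screen for publication bias by testing funnel plots (study
effect sizes against their standard errors) for asymmetry, usually with
Egger's regression or Duval & Tweedie's trim-and-fill. For the
**standardized mean difference** (SMD: Cohen's *d*, Hedges' *g*) this
workflow is structurally unsound, because the SMD's standard error depends
on the observed effect itself:

```
SE_d^2 = (n_c + n_i)/(n_c * n_i) + d^2 / (2 (n_c + n_i))
```

Among equally sized studies, the ones that happened to observe a larger
effect get a larger SE. Whenever a real effect is present, unbiased
SMD-vs-SE funnel plots shear — small observed effects drift to the upper
left, large ones to the lower right — and asymmetry tests reject data that
contain no bias at all. The artifact is worst exactly where SMDs are most
used: many, individually small studies, as in preclinical meta-analysis.

`funnelbias` implements, from arm-level summaries (mean, SD, n per group):

- **Effect measures** with their SEs: raw mean difference (RMD), Cohen's
  *d*, Hedges' *g* (small-sample correction `J = 1 - 3/(4m - 1)`, variance
  `J^2 var(d)`), and the normalized mean difference (NMD, percent of the
  control-vs-sham deficit).
- **Pooling**: fixed-effect and DerSimonian–Laird random-effects.
- **Asymmetry tests**: Egger-type weighted regression with a selectable
  precision predictor — the SE (classic Egger) or `1/sqrt(n)`, the
  sample-size-based ordinate that breaks the SMD–SE coupling — plus the
  Begg–Mazumdar rank-correlation test.
- **Trim-and-fill** (L0/R0 estimators, random-effects centring).
- **Monte-Carlo simulation** of whole meta-analyses (small 12–30-subject or
  large 60–320-subject studies, true effect 0/5/10 outcome units, optional
  stepwise significance censoring of 10%/50%/90% per p-value stratum) to
  measure false-positive rates and power of every measure/predictor
  combination.
- **Reporting**: funnel-plot construction/plotting and a one-call CSV
  re-analysis path (`reanalyze_csv()`), plus a thin CLI
  (`inst/scripts/funnelbias`).

## Worked example

Simulate 1000 unbiased meta-analyses of 300 small studies with a true
effect of 10 outcome units (true SMD = 1), and test every funnel variant:

```r
library(funnelbias)

cfg <- scenario_config(k_studies = 300, size_class = "small", delta_mu = 10,
                       reps = 1000, seed = 11, measures = c("RMD", "SMD_g"))
run_scenario(cfg, predictors = c("SE", "inv_sqrt_n"), trimfill = FALSE)
#> Scenario: 300 small studies/meta-analysis, delta_mu = 10, unbiased, 1000 reps (seed 11)
#>   measures: RMD, SMD_g
#>  measure  predictor egger_reject_pct egger_p_median pooled_mean
#>      RMD         SE              6.3       4.71e-01      10.000
#>    SMD_g         SE            100.0       1.94e-14       0.952
#>      RMD inv_sqrt_n              5.7       5.20e-01      10.000
#>    SMD_g inv_sqrt_n              5.2       5.12e-01       0.952
```

Every one of these 1000 meta-analyses is bias-free, yet the SMD-vs-SE
funnel is declared asymmetric 100% of the time (median Egger p ~ 2e-14).
The same data expressed as RMD, or the same SMDs tested against
`1/sqrt(n)`, reject at the nominal ~5%.

The per-dataset workflow:

```r
m <- simulate_meta(scenario_config(k_studies = 30, delta_mu = 10,
                                   seed = 1, measures = "SMD_g"))$SMD_g
egger_test(m, "SE")
#> Egger regression test for funnel-plot asymmetry
#>   predictor: standard error (k = 30)
#>   asymmetry coefficient: 3.2377 (SE 1.6380)
#>   t = 1.9766, df = 28, p = 0.05801
egger_test(m, "inv_sqrt_n")
#>   predictor: 1/sqrt(n) (k = 30)
#>   asymmetry coefficient: -3.0392 (SE 3.8497)
#>   t = -0.7895, df = 28, p = 0.4365
trim_and_fill(m)
#> Duval-Tweedie trim-and-fill
#>   estimated missing studies on the left side: 1 (L0 estimator)
#>   adjusted pooled estimate: 0.8597 (SE 0.0988)
```

One 30-study unbiased meta-analysis with a true SMD of 1: the SE-based
Egger test is already borderline (p = 0.058), the sample-size-based test is
unremarkable (p = 0.44), and trim-and-fill "corrects" the pooled *g*
downward to 0.86 — an underestimate typical of SMD funnels, since the
imputation mistakes the artifactual shear for missing studies.

Your own data go through the same functions: `read_arms_csv()` /
`read_effects_csv()` → `compute_effects()` → `egger_test()` /
`begg_test()` / `trim_and_fill()` / `build_funnel()`, or in one call,

```r
reanalyze_csv("effects.csv", predictors = c("SE", "inv_sqrt_n"),
              json = "report.json", svg = "funnel")
```

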