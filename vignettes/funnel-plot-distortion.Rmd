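---
title: "Methods: effect measures, funnel-plot asymmetry, and the SMD-SE artifact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect measures, funnel-plot asymmetry, and the SMD-SE artifact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelbias)
```

# The problem

Funnel plots — study effect sizes against a precision measure — are the
standard visual and analytical device for detecting small-study effects and,
by extension, suspected publication bias in a meta-analysis. The logic
requires that, absent bias and heterogeneity, the plot be symmetric around
the pooled effect: imprecise studies scatter more, but scatter evenly.

That premise silently fails for the standardized mean difference (SMD). Its
standard error is a function of the observed effect itself:

$$SE_d = \sqrt{\frac{n_{ctrl}+n_{int}}{n_{ctrl}\,n_{int}} +
  \frac{d^2}{2(n_{ctrl}+n_{int})}},$$

so among studies of identical size, the ones that happened to observe a
larger effect are assigned a larger SE. When a real effect is present, the
plot shears: small observed effects drift to the upper left, large ones to
the lower right. Asymmetry tests then reject in unbiased data — most
severely when the studies are individually small (the second term is
relatively large) and numerous (power to detect the shear grows with the
study count). Meta-analyses of preclinical animal studies combine both.

This package provides the effect measures, the asymmetry tests, the
trim-and-fill adjustment, and a Monte-Carlo engine to quantify when the
artifact occurs and to evaluate the two remedies: a sample-size-based
precision estimate ($1/\sqrt{n}$), and the normalized mean difference (NMD).

# Effect measures

For one study with control and intervention arms $(M, SD, n)$:

* **RMD** (raw mean difference): $M_{int} - M_{ctrl}$, with
  $SE^2 = SD_{int}^2/n_{int} + SD_{ctrl}^2/n_{ctrl}$. The SE involves only
  the arm SDs and sizes — never the effect.
* **Cohen's d**: the RMD divided by the pooled SD
  $SD_{pooled}^2 = \{(n_{ctrl}-1)SD_{ctrl}^2 + (n_{int}-1)SD_{int}^2\}/(n_{ctrl}+n_{int}-2)$,
  with the $SE_d$ above.
* **Hedges' g**: $g = J\,d$ with the small-sample correction
  $J = 1 - 3/(4m-1)$, $m = n_{ctrl}+n_{int}-2$, and $var(g) = J^2 var(d)$.
  The exact gamma-ratio correction
  $J = \Gamma(m/2) / \{\sqrt{m/2}\,\Gamma((m-1)/2)\}$ is available via
  `exact_j = TRUE`; the two differ by less than $10^{-3}$ for $m \ge 4$.
  The widely used approximation is the default. Alternative variance
  formulas circulate (e.g. substituting $g^2$ for $d^2$, or the exact
  noncentral-t variance); `funnelbias` uses $J^2 var(d)$ with $var(d)$ as
  printed above, which keeps the estimate/variance pair internally
  consistent with the correction factor.
* **NMD**: the intervention effect as a percentage of the control-versus-
  sham deficit, $100\,(M_{int}-M_{ctrl})/(M_{ctrl}-M_{sham})$, with
  $SE^2 = (100\,SD_{ctrl}/(M_{ctrl}-M_{sham}))^2/n_{ctrl} +
  (100\,SD_{int}/(M_{ctrl}-M_{sham}))^2/n_{int}$. The deficit is treated as
  a fixed per-study scaling: the sham arm contributes only its mean, not
  its SD or size. The literal formula is negative whenever the intervention
  moves the outcome toward the sham value, in either lesion direction; by
  default (`orient_improvement_positive = TRUE`) the sign is flipped so
  improvement reads as a positive percentage (25 means a 25% recovery of
  the deficit).

```{r}
s <- study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10),
                sham = arm_summary(70, 4, 5))
raw_mean_difference(s)
hedges_g(s)
normalized_mean_difference(s)
```

# Pooling

`pool_fixed()` is plain inverse-variance pooling. `pool_random()` uses the
closed-form DerSimonian-Laird moment estimator of $\tau^2$ (truncated at
zero) with a plain Wald standard error. DL was chosen over iterative
estimators (REML, Paule-Mandel) because it is deterministic, closed-form,
and the historical default of the R meta-analysis stack; at the study
counts this package targets (30-3000) the pooled means are insensitive to
the choice. No Hartung-Knapp adjustment is applied.

# Egger-type asymmetry regression

`egger_test()` regresses the effects $\theta_i$ on a precision ordinate
$x_i$ by weighted least squares with weights $1/x_i^2$, and tests the
coefficient of $x_i$ two-sided against $t_{k-2}$.

* With $x_i = se_i$ this is **algebraically identical** to Egger's classic
  intercept test (OLS of $\theta_i/se_i$ on $1/se_i$, testing the
  intercept); the test suite asserts the identity to $10^{-10}$ and
  verifies numerical agreement with `metafor::regtest(model = "lm")`.
* With $x_i = 1/\sqrt{n_i}$ ($n_i$ the total study sample size) the same
  construction is applied to the sample-size-based funnel plot, with
  weights $n_i$. The weights follow the plotted precision rather than
  staying at $1/se_i^2$ deliberately: the test is Egger's regression *of
  the funnel plot as constructed*. Keeping SE-based weights under the
  $1/\sqrt{n}$ predictor would re-import the SMD-SE coupling through the
  weights and measurably inflates the false-positive rate of the otherwise
  sound sample-size ordinate.

The classic weighted-LS form (a fixed-effect, multiplicative-dispersion
model) was preferred over a random-effects meta-regression variant: under
stepwise censoring the induced heterogeneity inflates $\tau^2$, and
random-effects weights then visibly blunt the test's power to detect the
very bias being simulated.

`begg_test()` is the Begg-Mazumdar rank correlation: Kendall's tau-b
between the fixed-effect-standardized deviations
$(\theta_i-\hat\mu_F)/\sqrt{se_i^2 - SE(\hat\mu_F)^2}$ and the sampling
variances, with the tie-corrected normal approximation for $S$. It responds
to the same funnel shear as the Egger test, with somewhat less power.

# Trim-and-fill

`trim_and_fill()` implements the Duval-Tweedie iteration with the rank-based
$L_0$ estimator (default; $R_0$ behind a flag), centring every iteration on
the DerSimonian-Laird random-effects estimate. The missing side defaults to
the side opposite the pooled effect's direction (`side = "auto"`): if the
intervention appears beneficial, the suspected-unpublished studies are the
small/negative ones. Imputed studies mirror the trimmed studies around the
final trimmed centre and inherit their source study's SE and sample sizes;
the adjusted estimate is the random-effects pool of observed plus filled
studies.

Numerical choices worth knowing:

* Deviations from the centre are snapped to a $10^{-8}$ relative tolerance
  and ranked with average ranks. This makes exactly mirrored studies tie
  and an exactly central study count for neither side, so a perfectly
  symmetric dataset yields $k_0 = 0$ regardless of floating-point noise in
  the centre. On continuous data (no exact ties) the algorithm agrees with
  `metafor::trimfill(estimator = "L0")`, which the tests verify.
* The iteration stops when $k_0$ stabilizes, with a cap of 50 iterations
  (exceeding it raises an error; in practice convergence takes a handful).
* Strict idempotence — re-running on the observed-plus-filled set imputing
  nothing further — holds for symmetric inputs, but on realistic censored
  data a re-run typically re-imputes one or two studies. This is a property
  of the $L_0$ estimator itself (the reference implementation behaves
  identically) caused by the adjusted centre differing slightly from the
  mirror centre.

# The simulation engine

`scenario_config()` + `run_scenario()` generate meta-analyses of two-arm
studies and measure the operating characteristics of the tests. The
defaults emulate a preclinical outcome scale (functional-imaging-like
scores): control subjects $N(30, 10^2)$; the intervention shifts the mean
by `delta_mu` (0, 5, 10 give true SMDs of 0, 0.5, 1); *small* studies draw
the intervention arm size uniformly from 7-14 with the control arm within
±2 (totals 12-30, control range 5-16); *large* studies draw 40-150 with the
control within ±20 (totals 60-320). The joint rule — intervention size
uniform, control an independent uniform offset from it — is the simplest
rule consistent with those published ranges. Sham arms have 4-6 subjects
from $N(70, 4^2)$, a typical sham-group size.

Subject-level outcomes are drawn and summarized to per-arm mean/SD/n
(`sampling = "subject"`, the default); `sampling = "summary"` draws the arm
mean from $N(\mu, \sigma^2/n)$ and the SD from the scaled-chi distribution,
which is distributionally identical and faster for very large scenarios.

Publication bias is induced by **stepwise censoring**
(`censor_studies()`): each study's two-sided pooled-variance Student t-test
p-value assigns it to a stratum, and the study survives with probability
0.9 ($p < 0.05$), 0.5 ($0.05 \le p < 0.10$) or 0.1 ($p \ge 0.10$).
Censored meta-analyses keep their surviving studies; they are not topped
back up, so the realized study count shrinks (tracked in the summary).

Reproducibility: one root seed per scenario spawns per-repetition
L'Ecuyer-CMRG streams, so repetitions are order-independent and the whole
`ScenarioSummary` is a deterministic function of the configuration.
Repetitions that end with fewer than 3 studies after censoring are counted
as degenerate and excluded from test aggregation (a practically
probability-zero event at the default parameters).

## The NMD normalization in simulated data

A subtlety with real teeth. Evaluating the NMD formula with each simulated
study's *realized* control mean in the denominator makes the estimate and
its SE share the random quantity $(M_{ctrl}-M_{sham})$; the control mean's
sampling error then couples them, and an Egger test on NMD-vs-SE funnels of
*unbiased* data rejects massively — the very artifact the NMD is supposed
to avoid, and a direct contradiction of the NMD's error model, in which the
SE is independent of the effect because the deficit is a fixed scaling.

The generator therefore normalizes each study by the **design deficit
carrying only sham sampling error**: the configured control baseline (30)
minus the study's realized sham mean (`nmd_baseline = "design"`, the
default). This matches the NMD's own assumption that the lesioned baseline
is an anchored reference, while retaining the sham arm's finite-sample
noise. The fully literal alternative (`nmd_baseline = "realized"`) is
available for studying the coupling itself. For *user data* the effects
module always evaluates the literal formula — realized means are all a real
meta-analyst has — and `compute_effects()` accepts an explicit
`nmd_deficit` when a better-anchored deficit is known.

## What the generator does and does not emulate

It emulates: realistic arm sizes and their dispersion, true-effect
magnitudes typical of animal studies, per-study sham references, and
p-value-targeted selective publication. It does **not** emulate: unequal
arm variances, non-normal outcomes, genuine between-study heterogeneity
($\tau^2 > 0$ by construction only via the artifact), correlated effects
from shared control groups, or outcome-level selective reporting. Passing
simulation-based tests therefore demonstrates the artifact and the
remedies under clean conditions; real datasets add heterogeneity that can
either mask or mimic asymmetry.

# Problem sizes used by the test suite

The packaged checks run each scenario at 1000 repetitions — the scale at
which the rejection percentages have Monte-Carlo standard errors under one
point — with 30-study and 300-study meta-analyses of small (12-30 subjects)
or large (60-320 subjects) studies; a full run takes well under a minute on
one core. Unit and property tests use small synthetic instances with frozen
hand-computed expectations, plus independent cross-checks of the pooling,
regression, rank-correlation and trim-and-fill routines against `metafor`
on random inputs.

# Known limitations

* The NMD SE ignores the sham arm's SD and size by construction; for tiny
  sham groups the reported SE understates the true uncertainty.
* DerSimonian-Laird is the only pooling estimator; heterogeneity-heavy
  datasets may warrant REML or Paule-Mandel (use a dedicated meta-analysis
  package for pooling if that matters — the asymmetry machinery here is
  agnostic to where the centreline comes from).
* Trim-and-fill assumes the suppressed studies are the exact mirror images
  of observed ones; its adjusted estimate is a sensitivity analysis, not a
  corrected truth — and under SMD-SE distortion it systematically
  *under*-corrects toward zero.
* Egger-type tests detect small-study effects of any origin; a rejection is
  evidence of asymmetry, not proof of publication bias.
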