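Package: funnelbias
Title: Funnel-Plot Asymmetry and Publication-Bias Assessment for
    Continuous Effect Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing publication bias in meta-analyses of
    continuous outcomes. Computes raw, standardized (Cohen's d, Hedges' g)
    and normalized mean differences with their standard errors from
    arm-level summaries, fits fixed- and random-effects (DerSimonian-Laird)
    pooled estimates, tests funnel-plot asymmetry with Egger-type weighted
    regression under interchangeable precision estimates (standard error or
    inverse square root of the sample size) and with the Begg-Mazumdar rank
    correlation, and adjusts for suspected missing studies with Duval and
    Tweedie's trim-and-fill. A Monte-Carlo engine simulates meta-analyses of
    small or large two-arm studies, optionally censored by a stepwise
    significance filter, to quantify false-positive asymmetry rates caused
    by the artifactual coupling between the standardized mean difference
    and its standard error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
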