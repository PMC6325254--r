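Package: metadisc
Title: Meta-Analysis of Dopamine PET Correlates of Reward Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes published correlations between striatal dopamine PET
    measures and reward-discounting behavior onto a common signed Fisher-z
    scale, fits random-effects meta-regression models by restricted maximum
    likelihood with heterogeneity statistics (Cochran's Q, I-squared) and
    AIC-based model comparison, and provides publication-bias diagnostics
    (an Egger-type precision-moderator test and funnel-plot data). Also
    implements the underlying behavioral model: hyperbolic discounting of
    delayed, risky, and effortful monetary rewards with a softmax choice
    rule, fit to trial-level choice data by maximum likelihood, plus
    synthetic-data generators for both the choice tasks and effect-size
    collections so that every stage of the pipeline can be tested against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
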