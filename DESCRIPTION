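Package: noisequity
Title: Cumulative Workplace and Transportation Noise Inequity Analysis
Version: 0.1.0
Authors@R:
    person("noisequity", "maintainers", email = "maintainers@noisequity.org",
           role = c("aut", "cre"))
Description: Quantifies racial and ethnic inequities in cumulative noise
    pollution at the census-tract level. Provides Monte Carlo estimators of
    the tract-level prevalence of hazardous workplace noise (8-h TWA > 85
    dBA, via a job-exposure matrix) and transportation noise (24-h LAeq >
    55 dBA, aggregated from census blocks), exposure-risk ratios with
    bootstrap confidence intervals, historical redlining scores and
    mortgage-discrimination indices, quintile-exposure generalized linear
    models with natural-spline and tensor-product spatial smooths, and a
    seeded synthetic census-geography generator with recorded ground truth
    for validation. A command-line pipeline orchestrates all stages into a
    reproducible, manifest-tracked run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    splines,
    mgcv,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
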