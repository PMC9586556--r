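Package: eoi
Title: Ellipse of Insignificance Fragility Analysis for Dichotomous Outcome Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic fragility analysis for 2x2 dichotomous-outcome
    contingency tables. The locus of simultaneous recoding displacements in
    the experimental and control arms at which a chi-squared test loses
    significance is an inclined ellipse (the ellipse of insignificance);
    its nearest point to the origin, axis intercepts and enclosing integer
    polygon yield exact tolerance thresholds for miscoding in either arm or
    both at once. These geometric bounds combine with the sensitivity and
    specificity of the endpoint test to flag reported results whose apparent
    significance cannot survive the test's intrinsic misclassification.
    Includes a classic Fisher-exact fragility index for comparison,
    brute-force lattice oracles, a seeded fixture-table generator, batch
    processing of delimited tables, JSON reports and plot-ready geometry
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
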