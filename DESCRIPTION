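Package: mrpathway
Title: Two-Sample Mendelian Randomization with Mediation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens built
    on GWAS summary statistics: reading, validating and harmonizing
    per-variant association tables onto a common effect-allele frame;
    selecting independent, sufficiently strong genetic instruments
    (p-value threshold, greedy LD clumping, F-statistic filter, Steiger
    directionality filter); five causal estimators (Wald ratio, inverse
    variance weighted, MR-Egger, weighted median, and mode-based methods)
    with odds-ratio reporting; sensitivity analyses (Cochran's Q, Egger
    intercept, leave-one-out, funnel data, Steiger directionality);
    two-step product-of-coefficients mediation across
    exposure-mediator-outcome triples with effect decomposition; batch
    screening with Benjamini-Hochberg false discovery rate control; and a
    fully seeded synthetic-data generator producing three-node cohorts and
    their marginal summary statistics so every pipeline stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
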