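Package: twostepmr
Title: Two-Step Multivariable Mendelian Randomisation Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation toolkit for decomposing the
    effect of an exposure on a binary outcome into direct and mediator-specific
    indirect effects. Provides GWAS summary-statistic import, instrument
    selection by p-value filtering and greedy LD clumping, effect-allele
    harmonisation with palindromic-SNP frequency inference, univariable
    estimators (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median) with Cochran's Q and Egger-intercept diagnostics, regression-based
    multivariable MR with conditional instrument-strength statistics,
    product-of-coefficients and difference-method mediation with delta-method
    proportion-mediated intervals over arbitrary mediator combinations, a
    seeded synthetic GWAS generator with known causal truth for validation,
    traditional regression-based mediation on individual-level data, and a
    config-driven end-to-end pipeline including reverse-MR checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
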