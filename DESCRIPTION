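Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics, organised as a bidirectional, two-step mediation
    pipeline. Covers reading, validation and allele harmonization of
    summary-statistic tables; instrument selection (genome-wide significance,
    LD clumping, outcome-association and confounder exclusion, F-statistic
    strength filtering); a causal-effect estimator suite (Wald ratio,
    fixed/random-effects inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode); sensitivity diagnostics (Cochran's Q, Egger
    intercept, Steiger directionality, leave-one-out, funnel/scatter tables);
    product-of-coefficients mediation with the Sobel test and the two-stage
    screening cascade; and a seeded synthetic-cohort generator with known
    causal structure, including a two-stage least squares estimator, so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
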