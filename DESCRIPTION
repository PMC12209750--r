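Package: gatescores
Title: Genome-Wide Aggregated Trans Effects (GATE) Scores for Core-Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs genome-wide aggregated trans effects (GATE) scores
    from QTL summary statistics and a linkage-disequilibrium reference
    panel, and tests them for association with a binary disease in a
    genotyped cohort. Implements p-value filtering and clumping of trans
    eQTL/pQTL associations, LD-corrected multivariable weights with a
    pseudoinverse for ill-conditioned clumps, per-individual locus scores
    aggregated genome-wide per gene, the Hill-number effective number of
    trans-QTLs, efficient score tests under a covariate-only logistic null
    with SD-standardized log odds ratios, Mendelian randomization that
    marginalizes over a distribution of direct (pleiotropic) instrument
    effects, and the filtering and validation criteria used to nominate
    putative core genes under the omnigenic sparse-effector model. A
    synthetic-data module simulates LD block structure, QTL studies and
    disease cohorts with core-gene-mediated risk so the whole pipeline is
    testable end to end without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
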