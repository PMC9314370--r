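Package: vqtlscan
Title: Genome-Wide Variance QTL Analysis via Heteroscedasticity Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection of variance quantitative trait loci (vQTLs): loci
    associated with differences in trait variance across genotypes rather
    than (only) trait means. Implements four heteroscedasticity tests for
    biobank-scale association scans -- a linear mixed model with a
    genotype-dependent random effect, a variance-component model fitted by
    constrained maximum likelihood, a quadratic extension of the
    Breusch-Pagan squared-residual regression, and a chi-square regression
    -- together with their boundary mixture null distribution,
    likelihood-ratio pseudo-R-squared effect sizes, Levene
    (Brown-Forsythe) comparison tests, blood-pressure-style phenotype
    preparation, sample and variant filters, a genome-scan driver with a
    command-line entry point, and simulation machinery for null
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, withr
Suggests: testthat (>= 3.0.0), VariantAnnotation, SummarizedExperiment,
    GenomicRanges, S4Vectors, optparse, jsonlite, parallel
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
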