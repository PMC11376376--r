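Package: eqtlpanel
Title: eQTL Mapping of qPCR Expression Traits in Structured Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping expression quantitative trait loci (eQTLs) when
    gene expression is measured by RT-qPCR across a structured diversity panel
    of hybrids sharing a common tester parent. Covers delta-Ct normalization
    against multiple reference genes, replicate-based repeatability
    ("heritability") estimation, single-locus mixed-model genome-wide
    association scans with leave-one-chromosome-out kinship, clustering of
    significant SNPs into local and distant eQTLs via kinship-corrected
    linkage-disequilibrium windows, conditional (covariate) and subpanel scans
    for handling qPCR-specific artifacts (reference-gene eQTLs and primer-site
    polymorphisms), a ratiometric mixed model for dual-fluorescence promoter
    reporter assays, and a synthetic-panel generator with planted genetic
    architectures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
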