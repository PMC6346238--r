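Package: methcimp
Title: CIMP Methylome Subtyping and Replicative-History Analysis for
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Maintainer", "methcimp", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Panel-based CpG island methylator phenotype (CIMP) scoring and
    classification of 450K-style beta-value matrices, methylome landscape
    statistics (promoter methylation means, hyper-/hypomethylation calls
    against a sorted-cell reference, genomic-region and island-context
    enrichment, differentially methylated CpG identification by delta-beta
    and rank-sum FDR), linear epigenetic clocks (DNAm age with the adult-age
    anchored log-linear transform, mitotic age as a panel average), relative
    telomere length from qPCR Ct tables, and integrated promoter
    methylation-expression analysis of negative-binomial count data.
    Includes a synthetic-cohort generator with full ground truth so every
    stage is testable without array downloads, plus a config-driven pipeline
    runner and command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
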