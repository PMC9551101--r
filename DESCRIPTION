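Package: mircross
Title: miRNA Target-Set Crossover Enrichment and Cross-Disorder Convergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing studies that ask
    whether the predicted target genes of differentially expressed miRNAs
    converge on disease gene sets. Implements FPKM normalisation and a
    negative-binomial fold-change filter for miRNA count matrices, a
    target-score-weighted enrichment test based on Fisher's noncentral
    hypergeometric distribution ("gene crossover probability"), a
    second-level hypergeometric test of convergence between
    disorder-associated and shared-target miRNA sets with three-set Venn
    decomposition, and 2^-ddCt and percent-of-input quantification for
    qPCR read-outs. Includes seeded synthetic-data generators and a
    deterministic fixture so the full pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
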