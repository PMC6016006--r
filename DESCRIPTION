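Package: transmeta
Title: Multi-Study Transcriptome Meta-Analysis with miRNA Target Integration
Version: 0.1.0
Authors@R:
    person("Transmeta", "Developers", email = "transmeta@example.org",
           role = c("aut", "cre"))
Description: An integrated workflow for combining several case/control
    expression studies: study-level quality control with six concordance
    indices (IQC, EQC, AQCg, AQCp, CQCg, CQCp) and PCA-based inspection,
    per-study differential expression with a fudge-penalized t statistic,
    cross-study combination by Fisher's method and the maxP statistic with
    Benjamini-Hochberg control, miRNA differential expression with a
    sigma/sigma-max variance filter and p/q/fold-change thresholds,
    three-source miRNA targetome intersection restricted to 3'-UTR sites,
    hypergeometric gene-set over-representation, and assembly of a mixed
    gene-gene / miRNA-gene interaction network with hub extraction.  A
    synthetic-data generator with known ground truth makes every stage
    testable without external downloads, and a command-line driver runs the
    whole pipeline from plain-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
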