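Package: pmidecay
Title: Postmortem-Interval Effects on Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of postmortem-interval (PMI)
    associated changes in bulk gene expression. Provides a synthetic
    GTEx-like data generator with known ground truth, per-tissue
    preprocessing (RIN and PMI sample filters, quantile normalisation,
    log2 transform, low-expression filtering), hidden-confounder
    correction by PCA factor inference with PMI-correlation filtering,
    per-gene multiple linear regression of expression on PMI with
    Benjamini-Hochberg FDR control and a permutation gate, bootstrap
    sample-size power curves, a genotype-by-PMI interaction scan with
    minor-allele-frequency filtering, Levene's test for differential
    variability between short- and long-PMI groups, and Ward clustering
    of samples on PMI-associated genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    limma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    pheatmap
Config/testthat/edition: 3
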