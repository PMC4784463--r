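Package: mbfish
Title: Markov Blanket Repeated-Fishing Feature Selection for Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature selection for case-control and quantitative-phenotype
    omics data by a Markov Blanket repeated-fishing strategy (MBRFS).
    A single blanket is grown by forward admission under first-order
    conditional-independence testing (G-squared for categorical data,
    Wald tests from logistic or linear regression otherwise), with
    backward pruning of false positives and linkage-disequilibrium
    pruning of the candidate pool; the blanket is then emptied and the
    search repeated on the shrunken pool until a round returns at most
    two markers.  Includes a parametric block-LD genotype simulator with
    a logistic disease model, comparison methods (Cochran-Armitage trend
    test with Bonferroni or Benjamini-Hochberg correction, L1-penalised
    logistic regression, a single-round blanket search with full
    conditioning), and TDR/FDR/MCC benchmarking utilities with
    cluster-based scoring for markers embedded in LD blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
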