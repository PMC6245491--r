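Package: chromaim
Title: Ancestry-Informative SNP Panels from a Single Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs small panels of ancestry-informative single
    nucleotide polymorphisms (SNPs) from one chromosome's genotypes in
    three stages: parameter-based selection of population-diagnostic SNPs
    (retention and modal-genotype fractions alpha and beta), density-based
    (DBSCAN) outlier selection of SNPs with unusual genotype profiles, and
    greedy pruning of SNPs with correlated per-continent single-marker
    performance. Panels are evaluated with a softmax (multinomial logistic)
    classifier for continental and pairwise sub-population ancestry
    prediction. Includes a hierarchical Balding-Nichols simulator of
    structured populations with planted fixed-difference markers, a
    Weir-Cockerham F_st estimator for validating it, and an end-to-end
    pipeline driver with reproducible, fully deterministic artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
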