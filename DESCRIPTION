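Package: snptree
Title: Hybrid SVM and Weighted ID3 Classification for Case-Control
    Genotype and Phenotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds case-control disease classifiers that integrate SNP
    genotypes with categorical and numeric phenotypes.  Genotype calls are
    encoded with a symmetric ten-level allele coding, pre-filtered by a
    genotypic chi-square association test, and combined with phenotypes
    into a single numeric dataset.  An RBF-kernel support vector machine,
    tuned by a C/gamma grid search, supplies per-attribute weights that
    scale the information-gain ratio of an ID3 decision tree; a threshold
    grid gates tree growth on the weighted score.  Includes PLINK text
    PED/MAP and delimited phenotype readers, class-mean imputation,
    stratified cross-validation with leakage-safe per-fold preprocessing,
    a three-model by three-dataset comparison harness, decision-rule
    extraction with a round-trip tree text format, and a seeded synthetic
    cohort generator with planted causal SNPs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
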