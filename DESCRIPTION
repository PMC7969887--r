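Package: hybridgs
Title: Genomic Selection for F1 Hybrid Breeding from Inbred Parent Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end genomic selection toolkit for F1 hybrid breeding
    programs built on inbred parent lines. Loads and quality-filters biallelic
    SNP genotype matrices, deterministically synthesizes the genotypes of all
    possible F1 hybrids from a panel of (near-)homozygous parents, builds
    additive and dominance genomic relationship matrices, fits GBLUP, Bayes B,
    Bayesian Lasso, RKHS kernel and random forest prediction models, estimates
    narrow-sense and additive-plus-dominance heritability, quantifies
    prediction accuracy by replicated cross-validation and across-population
    prediction, and ranks candidate parental combinations into selection
    classes. Includes a seeded breeding-population simulator (recurrent
    intercrossing followed by single seed descent, with additive-plus-dominance
    trait architectures) so the whole pipeline is testable with known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    randomForest
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
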