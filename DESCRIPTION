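Package: ovimp
Title: Genotype Imputation and Genomic Prediction in Multi-Breed Sheep Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for low- to medium-density SNP
    genotype imputation in purebred and crossbred sheep and its downstream
    effect on genomic prediction. Provides a multi-breed population simulator
    (Balding-Nichols breed divergence, half-sib family structure, F1 crosses),
    a SNP quality-control cascade, VanRaden genomic relationship matrices,
    relatedness-based imputation reference selection, a Li-Stephens haplotype
    copying HMM imputer with iterative phasing, imputation accuracy statistics,
    and in-house REML/GBLUP mixed-model machinery with progeny-test validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    methods,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
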