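Package: wssgblup
Title: Weighted Single-Step Genomic BLUP and Window-Based GWAS for
    Cattle Fertility Traits
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic evaluation for low-heritability beef
    cattle fertility traits, and the weighted single-step GWAS built on
    top of it.  Provides pedigree handling (Meuwissen-Luo inbreeding,
    sparse inverse numerator relationship matrix, indirect A22
    extraction), VanRaden genomic relationship matrices and the blended
    H-matrix inverse, Henderson mixed-model equations with AI-REML and
    EM-REML variance-component estimation, back-solving of SNP effects
    from genomic breeding values with iterative SNP variance weighting,
    a sliding 1-Mb window decomposition of additive genetic variance,
    and a gene-dropping herd simulator that generates pedigrees,
    genotypes and phenotypes with the variance structure the model
    assumes, so every stage of the analysis is testable without access
    to proprietary herdbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
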