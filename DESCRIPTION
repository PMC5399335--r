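Package: ovinepred
Title: Multi-Breed Genomic Prediction with GBLUP and BayesR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction in
    multi-breed and crossbred livestock populations, modelled on Australian
    sheep breeding designs. Provides a gene-dropping population simulator
    with configurable QTL architectures and two marker densities, SNP and
    sample quality control, VanRaden genomic and pedigree numerator
    relationship matrices, average-information REML variance components for
    a mixed model with maternal, breed-proportion and sire-by-flock terms,
    genomic BLUP via Henderson's mixed-model equations, a four-component
    BayesR Gibbs sampler, and relatedness-stratified validation of predicted
    breeding values against progeny-test estimated breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
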