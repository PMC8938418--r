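Package: satayEvol
Title: Gene Essentiality Polymorphism and Evolution from Transposon
    Insertion Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of saturated transposon insertional mutagenesis
    (SATAY/Tn-seq) libraries across multiple strains of a species. Collapses
    aligned reads into insertion maps, computes per-gene classifier features,
    trains and calibrates a random-forest gene essentiality classifier with
    depth-matched downsampling, assembles cross-strain essentiality matrices,
    detects essentiality polymorphism, counts essentiality changes on a strain
    phylogeny by parsimony, tests for among-gene rate variation
    (overdispersion and gamma/negative-binomial shape), runs allele-frequency
    matched SNP controls, estimates pairwise evolutionary correlations of
    essentiality under Felsenstein's threshold model, clusters covarying
    genes, tests complex/pathway concordance, and profiles intragenic
    transposon tolerance in ten coding segments. Includes a synthetic SATAY
    data generator so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    ape,
    randomForest,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    phytools,
    MASS,
    jsonlite,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Sequencing, Classification, Phylogenetics,
    FunctionalGenomics
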