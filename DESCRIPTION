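Package: crossBOA
Title: Breed Origin of Alleles in Crossbred Livestock Populations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a breed of origin (exotic or local) to every allele of
    crossbred animals by matching phased haplotypes against purebred haplotype
    libraries within windows ("cores") of consecutive SNPs, using
    fewest-mismatch (Hamming) matching with ties set to missing, and merging
    calls across core lengths and window offsets into consensus assignments at
    configurable agreement thresholds. Includes a stochastic crossbreeding
    simulator (drift-based founder breeds calibrated to a target fixation
    index, trait-based selection, repeated importation of exotic sires) that
    tracks the true founder origin of every allele through each meiosis, plus
    scoring utilities (yield, accuracy, Wright's FST, PCA) and phased-VCF
    input/output, so assignment performance can be evaluated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SNP, PopulationGenetics, Software
RoxygenNote: 7.3.3
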