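Package: clonegwas
Title: Genome-Wide Association Analysis for Clonal Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association studies in clonally replicated
    field trials of forest trees, modelled on an exome-capture study of
    Populus trichocarpa. Covers variant quality control (minor allele
    frequency, missingness, an exact Hardy-Weinberg test), BLUP-adjusted
    clone means and broad-sense heritability under a randomized block
    design, genomic-relationship kinship with principal-coordinate
    structure covariates, a kinship-corrected mixed-linear-model single-SNP
    scan, a sliding-window Poisson test for clusters of significant SNPs,
    and Hill-Weir linkage-disequilibrium decay fitting. A synthetic-data
    generator with block-structured linkage disequilibrium, population
    structure and known causal variants provides a ground-truth test bed,
    and a pipeline driver runs the stages end to end from a single
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    lme4,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
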