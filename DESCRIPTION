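Package: rohdiv
Title: Runs of Homozygosity, Pedigree Inbreeding and Genetic Diversity in
    Closed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring homozygosity and genetic diversity in
    pedigree-managed populations such as dog breeds. Implements Wright's
    pedigree inbreeding coefficient at configurable generation depth,
    window-based detection of runs of homozygosity (ROH) and the genomic
    inbreeding coefficient F_ROH from dense (sequence-like) and sparse
    (array-like) marker panels, ROH length-class decomposition,
    linkage-disequilibrium decay with Sved effective population size and
    per-generation inbreeding rate trajectories, per-marker two-cohort
    Weir-Cockerham F_ST, cross-cohort ROH-sharing windows, and
    homozygosity tallies within predicted variant-impact classes. A
    gene-dropping pedigree simulator with identity-by-descent tracking
    provides ground truth for every estimator. Reads and writes PLINK
    text (PED/MAP) and binary (BED/BIM/FAM) genotypes, VCF with ANN
    annotations, and PLINK-style .hom segment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
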