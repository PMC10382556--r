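Package: popsweep
Title: Genetic Diversity and Selection-Signature Scanning for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R: person("popsweep", "developers", role = c("aut", "cre"),
    email = "maintainers@popsweep.dev")
Description: A pipeline for genome-wide analysis of diversity and selection in
    multi-population diploid SNP genotype data. Reads and merges PLINK text and
    VCF datasets; applies a quality-control cascade (call rate, minor allele
    frequency, exact Hardy-Weinberg test, identity-by-descent relatedness
    pruning, linkage-disequilibrium pruning); computes population
    differentiation (allele frequency differences, chord and Reynolds
    distances, Weir-Cockerham FST with bootstrap intervals) and structure
    (principal components, local-outlier-factor screening, identity-by-state
    clustering); estimates contemporary and historical effective population
    size from linkage disequilibrium; detects runs of homozygosity and genomic
    inbreeding; and scans for selection signatures by combining per-SNP FST,
    the FLK test with a tree-derived kinship matrix, and cross-population
    extended haplotype homozygosity into a de-correlated composite of multiple
    signals (DCMS) with robust-covariance weighting, robust normal calibration
    and Benjamini-Hochberg false discovery control. Includes a Wright-Fisher
    forward simulator with recombination, selective sweeps and planted
    relatives so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    ape,
    phangorn,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
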