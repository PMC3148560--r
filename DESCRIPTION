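Package: haploSweep
Title: Relatedness-Weighted Haplotype Scans for Ongoing Selective Sweeps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection of ongoing selective sweeps from phased, polarized
    haplotype data using extended haplotype homozygosity (EHH) statistics.
    Implements the classical integrated haplotype score (iHS), a weighted
    variant (WiHS) in which each individual's contribution is scaled by its
    genome-wide uniqueness to correct for unequal relatedness and population
    structure, and the pairwise haplotype sharing score (PHS) as an O(n^2)
    comparator. Includes genetic-map fitting and coordinate conversion,
    allele-frequency standardization, window statistics with empirical
    significance, and a coalescent simulation harness (msprime backend over
    an ms-format boundary) for power and false-discovery-rate studies under
    panmictic, island, growth and bottleneck demographies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with msprime and tskit for the
    built-in coalescent simulation backend; not needed for scans on
    user-supplied data.
RoxygenNote: 7.3.3
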