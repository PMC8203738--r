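Package: popscan
Title: Selective-Sweep, Introgression and Haplotype Scans for Phased Population Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genomic scans for phased SNP panels: nucleotide
    diversity (theta-pi), Weir-Cockerham FST and log2 pi-ratio sweep criteria,
    cross-population extended haplotype homozygosity (XP-EHH), the XP-CLR
    composite-likelihood allele-frequency differentiation scan, a relative
    identity-by-descent (rIBD) introgression statistic, linkage-disequilibrium
    decay with accession subsampling, gene-region haplotype classification with
    median-joining networks and LSD phenotype comparisons, and per-SNP variance
    explained (PVE). Includes a forward-in-time Wright-Fisher simulator with
    recombination, hard sweeps and introgression pulses that produces phased
    panels with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
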