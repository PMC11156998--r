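Package: popgenscan
Title: Genome Diversity and Selection-Signature Scans from VCF Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic diversity and selection-signature analysis for
    multi-sample diploid SNP data. Reads biallelic VCF genotypes into a compact
    genotype matrix and computes per-population diversity (proportion of
    polymorphic SNPs, observed and expected heterozygosity, windowed nucleotide
    diversity, identity-by-state pairwise distance), detects runs of
    homozygosity with a scanning-window algorithm and derives the genomic
    inbreeding coefficient F_ROH, scans the genome for selective sweeps with
    sliding-window FST and pooled heterozygosity (Hp) Z-scores intersected in
    their 1% tails, and tests admixture with f3/f4 statistics using
    block-jackknife standard errors. Ships a Balding-Nichols cohort simulator
    with planted sweep windows and autozygous tracts so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
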