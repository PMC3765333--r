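Package: gfps
Title: Genome Fragmentation Phasing for Half-Sib Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint maximum-likelihood estimation of recombination fraction
    and maternal linkage disequilibrium at pairs of biallelic SNPs in
    half-sib families via an EM algorithm, with phase-posterior computation,
    multi-family pooled estimation, and a linkage-equilibrium-constrained
    baseline estimator.  Implements a genome fragmentation phasing strategy
    (GFPS) that reconstructs sire and progeny haplotypes from SNP-array
    genotypes, detects recombination events between haplotype blocks, and
    computes regions of identity between phased individuals.  Includes
    Monte-Carlo simulators of half-sib transmission, multi-family designs
    and phased chromosomes, a brute-force likelihood grid oracle, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
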