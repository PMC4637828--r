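Package: matrikin
Title: Population Structure, Matrilineal Culture and Historical Abundance
    from DNA Profiles and Stable Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing migratory networks of long-lived marine
    mammals from skin-biopsy DNA profiles (mtDNA control-region haplotypes
    plus multi-locus microsatellite genotypes) and stable-isotope profiles
    (delta-13C, delta-15N).  Implements genotype quality control (per-allele
    error rate, probability of identity, duplicate detection, Monte-Carlo
    Hardy-Weinberg exact tests), diversity and differentiation statistics
    (haplotype and nucleotide diversity, AMOVA-based F_ST and Phi_ST,
    Weir-Cockerham F_ST, Jost's D, permutation and Markov-chain exact tests),
    factorial correspondence analysis of genotypes, an isotope-genetics
    association battery (Kruskal-Wallis, AIC model weighting, matriline
    randomization F-ratio test, Ritland and Lynch-Ritland relatedness,
    Mantel tests), and Monte-Carlo conversion of coalescent genetic
    diversity (theta) into historical census abundance.  A synthetic-data
    module generates DNA and isotope profiles with known ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
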