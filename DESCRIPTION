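Package: PseudoDrift
Title: Genetic Drift, Consensus Genotyping and Individual Identification
    for a Pseudomelanism Allele in a Small Isolated Population
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher drift simulations for a recessive
    coat-pattern (pseudomelanism) allele in a small, isolated tiger
    population: bottleneck founding with logistic recovery, probability
    grids for the allele reaching high frequency, and time-to-fixation
    simulations with and without genetic rescue (one wild-type migrant per
    generation), validated against an exact absorbing-Markov-chain oracle.
    Also implements the supporting noninvasive-genetics workflow: multi-
    method consensus genotyping with a multiple-tube rule, individual
    identification from pairwise PI-HAT relatedness, probability of
    identity (PID and PID-sibs), locus/sample filter cascades, Wright's and
    Weir-Cockerham's F_ST, exact Hardy-Weinberg tests, per-individual
    inbreeding coefficients, and Mantel tests for isolation by distance,
    together with synthetic-data generators (HWE populations, pedigrees,
    allelic dropout, spatially structured populations) with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
biocViews: PopulationGenetics, Genetics, SNP, Software
RoxygenNote: 7.3.3
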