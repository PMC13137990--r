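Package: erosionscope
Title: Temporal Genomic Erosion Analysis and Non-Wright-Fisher Extinction
    Simulation for Declining Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying genomic erosion in declining populations
    sampled across time periods: hard-filtering and LD thinning of VCF
    genotypes, windowed nucleotide diversity, runs-of-homozygosity
    inbreeding coefficients (F_ROH), Grantham-score based classification of
    deleterious coding variants and realized genetic-load ratios, linkage
    disequilibrium based effective population size estimation with
    equal-sample resampling, and rank-sum based temporal comparison reports.
    Includes an individual-based non-Wright-Fisher forward simulator with an
    explicit genome architecture, a gamma distribution of fitness effects
    with threshold dominance, density-dependent survival under carrying
    capacity scenarios, and extinction-risk summaries, plus a synthetic
    cohort generator (Wright-Fisher diploid simulation with selfing and
    deleterious variation) so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
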