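Package: polybal
Title: Detection and Neutral-Retention Analysis of Balanced Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and simulation machinery for studying balanced
    phenotypic polymorphisms in natural populations: case-control
    allele-frequency association on low-coverage read counts with
    permutation-calibrated genome-wide significance, pseudo-haploid
    genotype calling and PC-corrected association, windowed
    balancing-selection scans (nucleotide diversity, Tajima's D, NCD1)
    with missing-data-aware estimators and recombination-matched null
    windows, neutral Wright-Fisher retention simulation under
    piecewise-constant demography, haplotype-phenotype association and
    diagnostic-SNP filtering, and simulation-based power analysis for
    dichotomous mate-choice trials. Includes seeded synthetic-data
    generators (Hardy-Weinberg populations with a dominant causal locus,
    Poisson low-coverage reads, coalescent haplotype windows, preference
    scores) so every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
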