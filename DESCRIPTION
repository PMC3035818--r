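Package: introscan
Title: Coalescent Outlier Scans and Poisson Dating of Interspecific
    Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and dates introgression between closely related
    species from multilocus data. Provides DnaSP-style diversity
    summaries on labelled sequence alignments (segregating sites,
    haplotype diversity, Jukes-Cantor corrected nucleotide diversity),
    Poisson divergence-time point estimates and significance bounds for
    introgressed haplotypes, a coalescent simulator for a two-population
    isolation model with infinite-sites mutation, a stepwise-mutation-model
    conversion to microsatellite allele states, microsatellite summary and
    differentiation statistics (Weir-Cockerham FST, Hedrick's
    standardized G'ST, rarefied allelic richness, inbred-line
    allele-drop correction, proportion-of-shared-alleles distances with
    neighbour-joining trees), and an FST/G'ST outlier scan against the
    simulated null distribution. A synthetic-data generator produces
    study-shaped inputs so the whole workflow runs without external
    deposits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
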