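Package: insertionfate
Title: Insertion Landscapes and Expression Variability of Exogenous
    Promoters on Circular Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analytical pipeline for studies that insert a strong reporter
    promoter at random positions across a circular bacterial chromosome and
    follow its early fate. Implements Cooper-Helmstetter age-structured
    gene-dosage models with a fork-level simulation oracle, circular
    sliding-window insertion coverage and origin-terminus asymmetry
    diagnostics, permutation enrichment tests of insertion/gene-list
    co-occurrence against a density-preserving shuffle null, one-sided
    Kolmogorov-Smirnov tests of AT-content bias around insertion sites,
    clone-level expression-noise scaling and outlier classification,
    sister-lineage expression divergence on microcolony trees, and a
    synthetic-data generator that emulates the processed form of the
    experimental data (ori-biased AT-correlated insertion landscapes,
    extrinsic plus telegraph-switching expression noise, fluorescence
    sorting, microcolony lineages) so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
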