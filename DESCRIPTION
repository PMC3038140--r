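Package: ssrmap
Title: Microsatellite Marker Development and Annotated Genetic Map Statistics
Version: 1.0.0
Authors@R:
    person("A.", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simple sequence repeat (SSR, microsatellite) marker
    development and for summarising annotated genetic linkage maps in outbred
    conifer pedigrees. Provides a perfect-SSR scanner with canonical motif
    normalisation and class de-duplication, the size-distributed primer-pair
    selection strategy used for multiplexed genotyping panels, Nei's unbiased
    gene diversity and class comparisons, segregation-distortion and
    missingness quality control for cross-pollinated (CP) full-sib pedigrees
    with a JoinMap-style 'loc' reader, genome-length (Chakravarti method 4)
    and map-coverage statistics with a Poisson marker-distribution test, a
    redundancy/paralogy classifier driven by clone, UniGene and alignment
    evidence, and seeded simulators that generate inputs with recorded truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
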