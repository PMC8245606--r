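Package: phagehostnet
Title: Biogeography of Phage-Host Cross-Infection Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for binary phage-bacterium cross-infection
    matrices sampled across sites and regions. Provides replicate consensus
    calling for spot assays, bipartite network structure metrics (connectance,
    NODF, nestedness temperature, Barber bipartite modularity via an adaptive
    BRIM optimizer) with equiprobable null-model significance tests,
    genotype/phenotype clustering rules (sequence types, genomic types from
    pairwise ANI/coverage, host-range phenotype groups), sympatric versus
    allopatric infection-rate statistics with a local-adaptation index and a
    quasi-binomial GLM F-test, distance-based community composition statistics
    (PERMANOVA, Mantel, PCoA, PCNM, vector fitting), and a synthetic-data
    generator with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
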