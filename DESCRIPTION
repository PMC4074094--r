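Package: prionNets
Title: Interaction and Functional Networks of Prion-Like Proteins in Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of the protein interaction and functional networks of
    prion, prionogenic and N/Q-rich prion-like proteins in budding yeast.
    Detects compositionally biased (asparagine/glutamine-rich) prion-like
    domains by binomial tail minimization, runs hypergeometric
    enrichment/depletion tests on interaction networks under an
    interaction-level counting convention with switchable background
    populations, performs Gene Ontology enrichment in three flavours
    (set membership, high-membership ranking with DAG collapse, and
    deduplicated interaction-based enrichment) with Holm-Bonferroni
    family-wise control, tests intrinsic-disorder elevation with a
    length-matched Monte-Carlo resampling null, and extracts interaction
    hubs. Ships curated prion protein sets and a synthetic-data generator
    with planted signal so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
biocViews: Proteomics, NetworkEnrichment, GO, Network, Software
RoxygenNote: 7.3.3
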