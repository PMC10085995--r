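Package: enrichsphere
Title: Mining Biome Enrichment Spheres from Microbiome Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies species and Gene Ontology (GO) functional annotations
    enriched in particular biomes from metagenome abundance tables, and grows
    "enrichment spheres": connected sets of GO terms on the ontology graph that
    are jointly enriched in one biome under a pooled (multivariate)
    hypergeometric gate, together with their enriched host species. Includes
    exact hypergeometric enrichment scans, an OBO 1.2 ontology parser, greedy
    sphere expansion with deterministic tie-breaking, a random-forest biome
    classifier with stratified cross-validation and micro/macro ROC summaries,
    stability selection, the enriched-biome selection rule for homolog
    supplementation, and a seeded Dirichlet-multinomial synthetic-data
    generator with planted spheres for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
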