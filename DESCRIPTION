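Package: ndkg
Title: Weighted Knowledge-Graph Construction and Ranked Retrieval for
    Neurodevelopmental-Disorder Web Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that annotates a corpus of cleaned web
    resources with controlled-vocabulary entities (dictionary-based named
    entity recognition), hierarchical latent Dirichlet allocation topics,
    multilabel resource categories, and gazetteer-resolved locations;
    assembles the annotations into a typed, weighted knowledge graph; and
    ranks resources for free-text queries by ordered weighted averaging
    (OWA) aggregation of edge weights under linguistic quantifiers. Entity
    relevance uses pivoted unique document-length normalization. Includes a
    seeded synthetic-data generator (corpora with planted topic mixtures,
    entity frequencies, category signals and locations) so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
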