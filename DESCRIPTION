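Package: rolhs
Title: Knowledge-Graph Infrastructure for a Radiation Oncology Learning
    Health System at Desk Scale
Version: 0.1.0
Authors@R:
    person("ROLHS", "Maintainers", email = "rolhs@example.org",
           role = c("aut", "cre"))
Description: Tools for building and exercising an ontology-driven clinical
    knowledge graph from relational-style radiotherapy records: a synthetic
    cohort generator with controlled data-quality faults, five-check ETL
    validation with a drop-on-failure policy and a mapping-completeness
    metric, declarative relational-to-RDF mapping (ClassMap/PropertyBridge
    style) into an in-memory triple store with Turtle serialization and
    basic-graph-pattern querying, synonym- and hierarchy-aware cohort
    search over a coded concept DAG, breadth-first random-walk corpora
    with word- and document-embedding models for patient-similarity
    ranking and five-group cluster evaluation, and grid-based cumulative
    dose-volume-histogram computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
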