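Package: ontoscape
Title: Deterministic 3D Visualization of OWL Ontology Class Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads OWL ontologies (RDF/XML or Turtle), extracts the named-class
    subsumption hierarchy using a first-listed-superclass rule, and computes a
    deterministic depth-stratified 3D layout in which every hierarchy depth
    occupies its own horizontal plane, upper-ontology scaffold terms can be
    pinned to fixed coordinates, and child generations are inserted tier by
    tier so the force simulation settles each stratum before the next one
    spawns. Nodes are colored by ontology prefix (OBO Foundry conventions),
    scenes are serialized to JSON with a structure-hash coordinate cache, term
    labels and synonyms are searchable, and a self-contained interactive HTML
    viewer can be exported. Includes a deterministic generator of synthetic
    multi-prefix OBO-style ontologies for offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
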