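# Fixture builders shared across tests.  Everything is constructed in code;
# nothing is downloaded.

mk_term <- function(iri, supers = character(), label = NA_character_,
                    synonyms = character(), deprecated = FALSE,
                    definition = NA_character_) {
  ontoscape:::new_raw_term(
    iri = iri, label = label, synonyms = synonyms, definition = definition,
    deprecated = deprecated, superclass_iris = supers
  )
}

mk_set <- function(..., source = "test://fixture") {
  ontoscape:::new_raw_term_set(list(...), source_identifier = source, format = "rdfxml")
}

obo <- function(prefix, id) {
  sprintf("http://purl.obolibrary.org/obo/%s_%07d", prefix, id)
}

# A hand-written RDF/XML document with full control over axiom order.
write_rdfxml_fixture <- function(classes, path = tempfile(fileext = ".owl")) {
  # classes: list of lists with fields iri, label, supers, synonyms,
  # deprecated, extra (verbatim XML lines inside the class element)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '         xmlns:obo="http://purl.obolibrary.org/obo/"',
    '         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">'
  )
  for (cl in classes) {
    lines <- c(lines, sprintf('  <owl:Class rdf:about="%s">', cl$iri))
    if (!is.null(cl$label)) {
      lines <- c(lines, sprintf('    <rdfs:label xml:lang="en">%s</rdfs:label>', cl$label))
    }
    for (s in cl$supers %||% character()) {
      lines <- c(lines, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>', s))
    }
    for (s in cl$synonyms %||% character()) {
      lines <- c(lines, sprintf('    <oboInOwl:hasExactSynonym>%s</oboInOwl:hasExactSynonym>', s))
    }
    if (isTRUE(cl$deprecated)) {
      lines <- c(lines, paste0(
        '    <owl:deprecated rdf:datatype="http://www.w3.org/2001/XMLSchema#boolean">',
        'true</owl:deprecated>'
      ))
    }
    lines <- c(lines, cl$extra %||% character(), '  </owl:Class>')
  }
  writeLines(c(lines, '</rdf:RDF>'), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced binary tree of given depth as a raw_term_set (root depth 0).
binary_tree_set <- function(depth, prefix = "OBI") {
  terms <- list()
  for (lvl in 0:depth) {
    for (k in seq_len(2^lvl)) {
      id <- 2^lvl + k - 1 # heap numbering
      sup <- if (lvl == 0) character() else obo(prefix, id %/% 2)
      terms[[length(terms) + 1]] <- mk_term(obo(prefix, id), supers = sup,
                                            label = paste("node", id))
    }
  }
  do.call(mk_set, terms)
}

# Small searchable fixture: the canonical "dog" synonym example.
dog_fixture <- function() {
  mk_set(
    mk_term(obo("NCBITAXON", 1), label = "root"),
    mk_term(obo("NCBITAXON", 2), supers = obo("NCBITAXON", 1), label = "Canis lupus"),
    mk_term(obo("NCBITAXON", 3), supers = obo("NCBITAXON", 2),
            label = "Canis lupus familiaris", synonyms = "dog",
            definition = "The domestic dog."),
    mk_term(obo("NCBITAXON", 4), supers = obo("NCBITAXON", 1), label = "Felis catus",
            synonyms = "cat")
  )
}
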