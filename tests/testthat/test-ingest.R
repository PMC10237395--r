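# OWL ingest: RDF/XML and Turtle parsing, annotation mapping, axiom order,
# prefix extraction.

test_that("RDF/XML parsing maps classes, labels, synonyms, deprecation and definitions", {
  p <- write_rdfxml_fixture(list(
    list(iri = obo("OBI", 1), label = "assay"),
    list(iri = obo("OBI", 2), label = "device", supers = obo("OBI", 1),
         synonyms = c("instrument", "apparatus")),
    list(iri = obo("OBI", 3), label = "old assay", supers = obo("OBI", 1),
         deprecated = TRUE),
    list(iri = obo("PATO", 4), label = "quality", supers = obo("OBI", 1),
         extra = "    <obo:IAO_0000115>A dependent entity.</obo:IAO_0000115>"),
    list(iri = obo("OBI", 5), label = "leaf", supers = obo("OBI", 2))
  ))
  raw <- parse_ontology(p)
  expect_s3_class(raw, "raw_term_set")
  expect_length(raw$terms, 5)
  expect_identical(raw$format, "rdfxml")

  t2 <- raw$terms[[obo("OBI", 2)]]
  expect_identical(t2$label, "device")
  expect_identical(t2$synonyms, c("instrument", "apparatus"))
  expect_false(t2$deprecated)
  expect_true(raw$terms[[obo("OBI", 3)]]$deprecated)
  expect_identical(raw$terms[[obo("PATO", 4)]]$definition, "A dependent entity.")
})

test_that("superclass axioms keep serialization encounter order", {
  a <- obo("OBI", 10); b <- obo("OBI", 11); c <- obo("OBI", 12)
  p1 <- write_rdfxml_fixture(list(
    list(iri = a, label = "A"), list(iri = b, label = "B"),
    list(iri = c, label = "C", supers = c(a, b))
  ))
  raw1 <- parse_ontology(p1)
  expect_identical(raw1$terms[[c]]$superclass_iris, c(a, b))

  # same classes, axioms serialized B-then-A: order must follow the bytes
  p2 <- write_rdfxml_fixture(list(
    list(iri = a, label = "A"), list(iri = b, label = "B"),
    list(iri = c, label = "C", supers = c(b, a))
  ))
  raw2 <- parse_ontology(p2)
  expect_identical(raw2$terms[[c]]$superclass_iris, c(b, a))
})

test_that("reparsing the same bytes yields an identical term set", {
  res <- generate_ontology(fixture_spec(
    n_terms = 60, n_prefixes = 3, multi_parent_fraction = 0.2,
    deprecated_fraction = 0.1, seed = 9
  ))
  r1 <- parse_ontology(res$path)
  r2 <- parse_ontology(res$path)
  expect_identical(r1$terms, r2$terms)
})

test_that("anonymous (restriction) superclasses are dropped, named ones kept", {
  a <- obo("OBI", 20); c <- obo("OBI", 21)
  p <- write_rdfxml_fixture(list(
    list(iri = a, label = "A"),
    list(iri = c, label = "C", extra = c(
      '    <rdfs:subClassOf>',
      '      <owl:Restriction>',
      sprintf('        <owl:onProperty rdf:resource="%s"/>', obo("RO", 1)),
      '      </owl:Restriction>',
      '    </rdfs:subClassOf>',
      sprintf('    <rdfs:subClassOf rdf:resource="%s"/>', a)
    ))
  ))
  raw <- parse_ontology(p)
  expect_identical(raw$terms[[c]]$superclass_iris, a)
})

test_that("first en-tagged label wins over other languages", {
  a <- obo("OBI", 30)
  p <- write_rdfxml_fixture(list(
    list(iri = a, extra = c(
      '    <rdfs:label xml:lang="de">Versuch</rdfs:label>',
      '    <rdfs:label xml:lang="en">assay</rdfs:label>'
    ))
  ))
  expect_identical(parse_ontology(p)$terms[[a]]$label, "assay")
})

test_that("Turtle parsing agrees with RDF/XML on the same content", {
  ttl <- tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix oboInOwl: <http://www.geneontology.org/formats/oboInOwl#> .",
    "@prefix obo: <http://purl.obolibrary.org/obo/> .",
    "# a comment",
    "obo:OBI_0000001 a owl:Class ; rdfs:label \"assay\"@en .",
    "obo:OBI_0000002 a owl:Class ;",
    "    rdfs:label \"device\"@en ;",
    "    oboInOwl:hasExactSynonym \"instrument\" ;",
    "    rdfs:subClassOf obo:OBI_0000001, obo:PATO_0000003 ;",
    "    rdfs:subClassOf [ a owl:Restriction ] .",
    "obo:PATO_0000003 a owl:Class ; rdfs:label \"quality\"@en ;",
    "    owl:deprecated \"true\"^^<http://www.w3.org/2001/XMLSchema#boolean> ."
  ), ttl)
  raw <- parse_ontology(ttl)
  expect_identical(raw$format, "turtle")
  expect_length(raw$terms, 3)
  t2 <- raw$terms[["http://purl.obolibrary.org/obo/OBI_0000002"]]
  expect_identical(t2$superclass_iris, c(
    "http://purl.obolibrary.org/obo/OBI_0000001",
    "http://purl.obolibrary.org/obo/PATO_0000003"
  ))
  expect_identical(t2$synonyms, "instrument")
  expect_true(raw$terms[["http://purl.obolibrary.org/obo/PATO_0000003"]]$deprecated)
})

test_that("error contracts: unreadable source, bad RDF, empty ontology", {
  expect_error(parse_ontology("/no/such/file.owl"), "cannot read ontology source")
  expect_error(parse_ontology("/no/such/file.owl"), "/no/such/file.owl")

  bad <- tempfile(fileext = ".owl")
  writeLines("<?xml version='1.0'?><RDF><mismatched></RDF>", bad)
  expect_error(parse_ontology(bad), "format error")

  empty <- tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'
  ), empty)
  expect_error(parse_ontology(empty), "empty ontology")
})

test_that("prefix extraction follows OBO PURL and fallback rules", {
  expect_identical(extract_prefix("http://purl.obolibrary.org/obo/OBI_0000070"), "OBI")
  expect_identical(extract_prefix("http://purl.obolibrary.org/obo/BFO_0000001"), "BFO")
  expect_identical(extract_prefix("http://www.w3.org/2002/07/owl#Thing"), "owl")
  expect_identical(extract_prefix("http://example.com/vocab/Term1"), "vocab")
  # lowercase obo prefixes are uppercased
  expect_identical(extract_prefix("http://purl.obolibrary.org/obo/so_0000001"), "SO")
  # purity on repeated application
  iris <- vapply(1:20, function(i) obo(c("GO", "CL", "PR")[i %% 3 + 1], i), "")
  expect_identical(extract_prefix(iris), extract_prefix(iris))
})
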