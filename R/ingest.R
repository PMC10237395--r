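# OWL ingest: read RDF/XML or Turtle and extract raw class records.
#
# The downstream hierarchy rule ("first listed superclass wins") is
# order-dependent, so this parser records superclass axioms in the order they
# are encountered in the serialization byte stream.  xml2 preserves document
# order for RDF/XML; the Turtle reader (see turtle.R) emits triples in source
# order by construction.

new_raw_term <- function(iri, label = NA_character_, synonyms = character(),
                         definition = NA_character_, deprecated = FALSE,
                         superclass_iris = character()) {
  structure(
    list(
      iri = iri, label = label, synonyms = synonyms,
      definition = definition, deprecated = isTRUE(deprecated),
      superclass_iris = superclass_iris
    ),
    class = "raw_term"
  )
}

new_raw_term_set <- function(terms, source_identifier, format) {
  iris <- vapply(terms, `[[`, "", "iri")
  if (anyDuplicated(iris)) {
    stop("duplicate IRIs in term set: ", paste(unique(iris[duplicated(iris)]), collapse = ", "))
  }
  names(terms) <- iris
  structure(
    list(terms = terms, source_identifier = source_identifier, format = format),
    class = "raw_term_set"
  )
}

#' @export
print.raw_term_set <- function(x, ...) {
  cat(sprintf(
    "<raw_term_set> %d classes from %s (%s)\n",
    length(x$terms), x$source_identifier, x$format
  ))
  invisible(x)
}

#' Extract the ontology prefix from a term IRI
#'
#' For OBO PURL IRIs of the shape `.../obo/<PREFIX>_<localid>` the uppercased
#' `<PREFIX>` is returned, matching OBO Foundry CURIE conventions.  Other IRIs
#' fall back to the last namespace token of the path (the segment before the
#' fragment for `#`-style IRIs, otherwise the second-to-last path segment), and
#' finally to the authority string.  Pure and deterministic.
#'
#' @param iri Character vector of IRIs.
#' @return Character vector of prefixes.
#' @examples
#' extract_prefix("http://purl.obolibrary.org/obo/OBI_0000070") # "OBI"
#' extract_prefix("http://www.w3.org/2002/07/owl#Thing") # "owl"
#' @export
extract_prefix <- function(iri) {
  vapply(iri, function(x) {
    if (!nzchar(x)) return("")
    m <- regmatches(x, regexec("^https?://purl\\.obolibrary\\.org/obo/([A-Za-z][A-Za-z0-9]*)_[^/#]+$", x))[[1]]
    if (length(m) == 2) return(toupper(m[2]))
    # fragment-style IRI: namespace is everything before '#'
    if (grepl("#", x, fixed = TRUE)) {
      ns <- sub("#.*$", "", x)
      seg <- basename(ns)
      if (nzchar(seg)) return(seg)
    }
    # path-style: local id is the last segment, namespace token the one before
    path <- sub("^[a-zA-Z][a-zA-Z0-9+.-]*://[^/]*", "", x)
    segs <- strsplit(path, "/", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    if (length(segs) >= 2) return(segs[length(segs) - 1])
    # unparseable: whole authority
    auth <- sub("^[a-zA-Z][a-zA-Z0-9+.-]*://([^/]*).*$", "\\1", x)
    if (identical(auth, x)) x else auth
  }, character(1), USE.NAMES = FALSE)
}

#' Parse an OWL ontology into raw class records
#'
#' Reads an OWL file (local path or HTTP/HTTPS URL) serialized as RDF/XML or
#' Turtle and returns one record per declared `owl:Class` with an IRI,
#' carrying its label (first `en`-tagged occurrence preferred), OBO-style
#' synonyms and textual definition, the `owl:deprecated` flag, and the list of
#' named superclass IRIs in the order the axioms appear in the serialization.
#' Anonymous superclasses (restrictions, blank nodes) are dropped.  Deprecated
#' terms are retained here; hiding them is downstream display policy.
#'
#' @param source Path or URL of the ontology file.
#' @param format One of `"auto"`, `"rdfxml"`, `"turtle"`.  `"auto"` sniffs the
#'   content (XML declaration / `<rdf:RDF`) and the file extension.
#' @param timeout Seconds allowed for a URL fetch (single GET, redirects
#'   followed, no retries).
#' @return A `raw_term_set`: a list with `terms` (named by IRI),
#'   `source_identifier`, and `format`.
#' @examples
#' owl <- generate_ontology(fixture_spec(n_terms = 20, seed = 1))
#' parse_ontology(owl$path)
#' @export
parse_ontology <- function(source, format = c("auto", "rdfxml", "turtle"),
                           timeout = 60) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1)

  is_url <- grepl("^https?://", source)
  path <- source
  if (is_url) {
    path <- tempfile(fileext = ".owl")
    old <- options(timeout = timeout)
    on.exit(options(old), add = TRUE)
    ok <- tryCatch(
      utils::download.file(source, path, quiet = TRUE, mode = "wb"),
      error = function(e) e, warning = function(w) w
    )
    if (inherits(ok, "condition") || !file.exists(path) || file.size(path) == 0) {
      stop("cannot read ontology source '", source, "': ",
           if (inherits(ok, "condition")) conditionMessage(ok) else "empty download")
    }
  } else if (!file.exists(path)) {
    stop("cannot read ontology source '", source, "': file not found")
  }

  if (format == "auto") {
    head_bytes <- readChar(path, nchars = 2048, useBytes = TRUE)
    format <- if (grepl("<\\?xml|<rdf:RDF|<RDF", head_bytes)) {
      "rdfxml"
    } else if (grepl("\\.(ttl|turtle)$", source, ignore.case = TRUE) ||
               grepl("@prefix|^PREFIX", head_bytes)) {
      "turtle"
    } else {
      "rdfxml"
    }
  }

  terms <- switch(format,
    rdfxml = parse_rdfxml(path, source),
    turtle = parse_turtle_terms(path, source)
  )
  if (length(terms) == 0) {
    stop("empty ontology: no owl:Class declarations found in '", source, "'")
  }
  new_raw_term_set(terms, source_identifier = source, format = format)
}

# --- RDF/XML ---------------------------------------------------------------

xml_local <- function(node) xml2::xml_name(node, ns = character())

rdf_resource <- function(node) {
  xml2::xml_attr(node, "rdf:resource", ns = c(rdf = NS_RDF))
}

rdf_about <- function(node, base) {
  a <- xml2::xml_attr(node, "rdf:about", ns = c(rdf = NS_RDF))
  if (!is.na(a)) return(a)
  id <- xml2::xml_attr(node, "rdf:ID", ns = c(rdf = NS_RDF))
  if (!is.na(id)) return(paste0(base, "#", id))
  NA_character_
}

parse_rdfxml <- function(path, source) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("RDF/XML format error in '", source, "': ", conditionMessage(e))
  )
  root <- xml2::xml_root(doc)
  base <- xml2::xml_attr(root, "xml:base", ns = c(xml = NS_XML))
  if (is.na(base)) base <- source
  ns_map <- xml2::xml_ns(doc)

  # Accumulators keyed by IRI; document order is preserved by appending.
  acc <- new.env(parent = emptyenv())
  order_seen <- character()
  declared <- character()

  get_rec <- function(iri) {
    if (!exists(iri, envir = acc, inherits = FALSE)) {
      assign(iri, list(
        labels = list(), synonyms = stats::setNames(
          vector("list", length(SYNONYM_IRIS)), names(SYNONYM_IRIS)
        ),
        definition = NA_character_, deprecated = FALSE, supers = character()
      ), envir = acc)
      order_seen <<- c(order_seen, iri)
    }
    get(iri, envir = acc, inherits = FALSE)
  }
  put_rec <- function(iri, rec) assign(iri, rec, envir = acc)

  # All top-level description blocks about a class, in document order:
  # owl:Class elements anywhere, plus rdf:Description elements typed owl:Class.
  blocks <- xml2::xml_find_all(doc, sprintf(
    "//*[local-name()='Class' and namespace-uri()='%s'] | //*[local-name()='Description' and namespace-uri()='%s']",
    NS_OWL, NS_RDF
  ))

  for (blk in blocks) {
    iri <- rdf_about(blk, base)
    if (is.na(iri) || !nzchar(iri)) next # anonymous class
    children <- xml2::xml_children(blk)
    blk_is_class <- xml_local(blk) == "Class"
    typed_class <- FALSE

    rec <- get_rec(iri)
    for (ch in children) {
      full <- element_iri(ch, ns_map)
      if (identical(full, IRI_RDF_TYPE)) {
        if (identical(rdf_resource(ch), IRI_OWL_CLASS)) typed_class <- TRUE
      } else if (identical(full, IRI_RDFS_SUBCLASSOF)) {
        sup <- rdf_resource(ch)
        if (is.na(sup)) {
          # nested node: accept only a named owl:Class child
          sub_children <- xml2::xml_children(ch)
          for (sc in sub_children) {
            if (identical(element_iri(sc, ns_map), IRI_OWL_CLASS)) {
              nested <- rdf_about(sc, base)
              if (!is.na(nested)) sup <- nested
            }
            break
          }
        }
        if (!is.na(sup)) rec$supers <- c(rec$supers, sup)
      } else if (identical(full, IRI_RDFS_LABEL)) {
        lang <- xml2::xml_attr(ch, "xml:lang", ns = c(xml = NS_XML))
        rec$labels <- c(rec$labels, list(list(text = xml2::xml_text(ch), lang = lang)))
      } else if (full %in% SYNONYM_IRIS) {
        scope <- names(SYNONYM_IRIS)[match(full, SYNONYM_IRIS)]
        rec$synonyms[[scope]] <- c(rec$synonyms[[scope]], xml2::xml_text(ch))
      } else if (identical(full, IRI_OBO_DEFINITION)) {
        if (is.na(rec$definition)) rec$definition <- xml2::xml_text(ch)
      } else if (identical(full, IRI_OWL_DEPRECATED)) {
        if (tolower(trimws(xml2::xml_text(ch))) %in% c("true", "1")) rec$deprecated <- TRUE
      }
    }
    put_rec(iri, rec)
    if (blk_is_class || typed_class) declared <- union(declared, iri)
  }

  assemble_terms(acc, order_seen, declared)
}

# Full IRI of an element (namespace-uri + local name), resolved through the
# document's namespace map (avoids an XPath evaluation per element).
element_iri <- function(node, ns_map) {
  nm <- xml2::xml_name(node, ns = ns_map)
  if (grepl(":", nm, fixed = TRUE)) {
    pfx <- sub(":.*$", "", nm)
    local <- sub("^.*:", "", nm)
    uri <- unname(ns_map[pfx])
    if (is.na(uri)) uri <- ""
  } else {
    local <- nm
    uri <- ""
  }
  paste0(uri, local)
}

# Turn accumulated per-IRI records into raw_terms for the declared classes.
assemble_terms <- function(acc, order_seen, declared) {
  keep <- order_seen[order_seen %in% declared]
  lapply(keep, function(iri) {
    rec <- get(iri, envir = acc, inherits = FALSE)
    # label: first "en"-tagged, else first seen
    label <- NA_character_
    if (length(rec$labels)) {
      langs <- vapply(rec$labels, function(l) if (is.na(l$lang)) "" else l$lang, "")
      en <- which(langs == "en")
      label <- if (length(en)) rec$labels[[en[1]]]$text else rec$labels[[1]]$text
    }
    # synonyms: dedupe in exact > narrow > broad > related priority,
    # document order within a scope
    syns <- unlist(rec$synonyms[names(SYNONYM_IRIS)], use.names = FALSE)
    syns <- if (is.null(syns)) character() else unique(syns)
    new_raw_term(
      iri = iri, label = label, synonyms = syns,
      definition = rec$definition, deprecated = rec$deprecated,
      superclass_iris = unique(rec$supers)
    )
  })
}
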