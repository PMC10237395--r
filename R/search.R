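# Term search and context: as-you-type lookup over labels and synonyms, and
# the dashboard view of a term (parent, children, definition, lookup-service
# links).  Lookup URLs are constructed, never fetched.

#' Search terms by label and synonyms
#'
#' Case-insensitive substring match against node labels and all synonym
#' scopes, so a colloquial synonym ("dog") finds the formally labelled term
#' ("Canis lupus familiaris").  Ranking: label-prefix matches first, then
#' label-substring matches, then synonym-only matches; ties broken by label
#' alphabetically (then IRI).  The empty query returns every term in label
#' order — the pull-down list of all terms.
#'
#' @param query Query string.
#' @param graph An `ontology_graph`.
#' @return The matching rows of `graph$nodes`, ranked.
#' @export
search_terms <- function(query, graph) {
  stopifnot(inherits(graph, "ontology_graph"), is.character(query), length(query) == 1)
  nodes <- graph$nodes
  ord_label <- order(tolower(nodes$label), nodes$iri)
  if (!nzchar(query)) {
    out <- nodes[ord_label, , drop = FALSE]
    row.names(out) <- NULL
    return(out)
  }
  q <- tolower(query)
  lab <- tolower(nodes$label)
  label_prefix <- startsWith(lab, q)
  label_sub <- !label_prefix & grepl(q, lab, fixed = TRUE)
  syn_hit <- vapply(nodes$synonyms, function(s) {
    length(s) > 0 && any(grepl(q, tolower(s), fixed = TRUE))
  }, TRUE)
  tier <- ifelse(label_prefix, 1L, ifelse(label_sub, 2L, ifelse(syn_hit, 3L, NA_integer_)))
  hit <- which(!is.na(tier))
  hit <- hit[order(tier[hit], tolower(nodes$label[hit]), nodes$iri[hit])]
  out <- nodes[hit, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Context of a term: parent, children, definition, lookup links
#'
#' Resolves a term's single chosen parent and its children from the rendered
#' forest, and constructs per-term pages on the OntoBee and EMBL-EBI OLS
#' lookup services.  The OntoBee URL carries the unmodified IRI as its `iri`
#' query parameter; the OLS URL uses the lowercased ontology prefix and the
#' double-percent-encoded IRI, per each service's published URL scheme.
#' Superclasses suppressed by the first-listed-parent rule are reported
#' separately in `suppressed_parents`.
#'
#' @param iri Term IRI (or OBO-style CURIE).
#' @param graph An `ontology_graph`.
#' @return A `term_context` list: `term`, `parent` (or `NULL`), `children`,
#'   `definition`, `ontobee_url`, `ols_url`, `suppressed_parents`.
#' @export
term_context <- function(iri, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  iri2 <- if (iri %in% graph$nodes$iri) iri else curie_to_obo_iri(iri)
  i <- match(iri2, graph$nodes$iri)
  if (is.na(i)) stop("term not found in graph: ", iri)
  nodes <- graph$nodes
  term <- nodes[i, , drop = FALSE]
  parent <- if (is.na(nodes$parent[i])) NULL else {
    nodes[match(nodes$parent[i], nodes$iri), , drop = FALSE]
  }
  kids <- nodes[!is.na(nodes$parent) & nodes$parent == iri2, , drop = FALSE]
  kids <- kids[order(tolower(kids$label), kids$iri), , drop = FALSE]
  row.names(kids) <- NULL
  prefix <- nodes$prefix[i]
  enc2 <- utils::URLencode(utils::URLencode(iri2, reserved = TRUE), reserved = TRUE)
  structure(
    list(
      term = term,
      parent = parent,
      children = kids,
      definition = nodes$definition[i],
      ontobee_url = paste0("https://ontobee.org/ontology/", prefix, "?iri=", iri2),
      ols_url = paste0("https://www.ebi.ac.uk/ols4/ontologies/", tolower(prefix),
                       "/classes/", enc2),
      suppressed_parents = graph$dropped_edges$dropped_parent[
        graph$dropped_edges$child == iri2
      ]
    ),
    class = "term_context"
  )
}

#' @export
print.term_context <- function(x, ...) {
  cat(sprintf("%s  <%s>\n", x$term$label, x$term$iri))
  if (!is.na(x$definition)) cat("  definition: ", x$definition, "\n", sep = "")
  cat("  parent: ", if (is.null(x$parent)) "(none: root)" else x$parent$label, "\n", sep = "")
  if (nrow(x$children)) {
    cat("  children:\n")
    for (l in x$children$label) cat("    - ", l, "\n", sep = "")
  } else {
    cat("  children: (none: leaf)\n")
  }
  if (length(x$suppressed_parents)) {
    cat("  suppressed superclasses: ", paste(x$suppressed_parents, collapse = ", "), "\n", sep = "")
  }
  cat("  OntoBee: ", x$ontobee_url, "\n  OLS: ", x$ols_url, "\n", sep = "")
  invisible(x)
}
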