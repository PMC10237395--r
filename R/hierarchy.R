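# Hierarchy construction: collapse the OWL subsumption graph to a rooted
# forest with the first-listed-superclass rule, detect standalone roots,
# apply the deprecation filter, and assign depth strata.

new_ontology_graph <- function(nodes, dropped_edges, source_identifier = NA_character_) {
  roots <- nodes$iri[is.na(nodes$parent)]
  thing <- roots[roots == IRI_OWL_THING]
  structure(
    list(
      nodes = nodes,
      roots = roots,
      standalone_roots = setdiff(roots, thing),
      dropped_edges = dropped_edges,
      source_identifier = source_identifier
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d nodes, %d edges, %d root(s) (%d standalone), max depth %s\n",
    nrow(x$nodes), sum(!is.na(x$nodes$parent)), length(x$roots),
    length(x$standalone_roots),
    if (all(is.na(x$nodes$depth))) "unset" else max(x$nodes$depth, na.rm = TRUE)
  ))
  invisible(x)
}

graph_edges <- function(graph) {
  has_parent <- !is.na(graph$nodes$parent)
  data.frame(
    child = graph$nodes$iri[has_parent],
    parent = graph$nodes$parent[has_parent],
    stringsAsFactors = FALSE
  )
}

#' Build a rooted forest from raw OWL class records
#'
#' Each class keeps a single parent: the first superclass listed in its
#' serialization that survives filtering.  A listed superclass survives if it
#' (still) exists among retained terms and accepting it would not close a
#' cycle; otherwise the next listed superclass is tried, and a term whose
#' candidates are exhausted becomes a standalone root.  `owl:Thing` is
#' materialized as a node whenever any term names it as a superclass or it is
#' declared.  With `hide_deprecated`, deprecated terms are removed before
#' parent selection and their non-deprecated descendants re-parent to the
#' nearest retained ancestor along the first-listed chain (or become
#' standalone roots).  Suppressed multi-inheritance edges are recorded in
#' `dropped_edges` for reporting; they are never rendered.
#'
#' @param raw A `raw_term_set` from [parse_ontology()].
#' @param hide_deprecated Remove `owl:deprecated` terms (default `TRUE`,
#'   matching the default display policy).
#' @return An `ontology_graph`: node table (`iri`, `prefix`, `label`,
#'   `synonyms`, `definition`, `deprecated`, `parent`, `depth`, `pinned`),
#'   `roots`, `standalone_roots`, and the `dropped_edges` side table.
#' @examples
#' owl <- generate_ontology(fixture_spec(n_terms = 30, seed = 2))
#' g <- build_graph(parse_ontology(owl$path))
#' g
#' @export
build_graph <- function(raw, hide_deprecated = TRUE) {
  stopifnot(inherits(raw, "raw_term_set"))
  terms <- raw$terms
  iris <- names(terms)
  deprecated <- vapply(terms, `[[`, TRUE, "deprecated")

  retained <- if (hide_deprecated) iris[!deprecated] else iris
  is_retained <- function(x) !is.na(match(x, retained))

  thing_needed <- IRI_OWL_THING %in% iris ||
    any(vapply(terms[retained], function(t) IRI_OWL_THING %in% t$superclass_iris, TRUE))

  # Nearest retained ancestor of a hidden term, following its first-listed
  # chain; memoized, cycle-guarded.
  nra_memo <- new.env(parent = emptyenv())
  nearest_retained_ancestor <- function(iri, seen = character()) {
    if (!is.null(nra_memo[[iri]])) return(nra_memo[[iri]])
    if (iri %in% seen) return(NA_character_)
    t <- terms[[iri]]
    if (is.null(t)) return(NA_character_)
    out <- NA_character_
    for (sup in t$superclass_iris) {
      if (is_retained(sup)) {
        out <- sup
        break
      }
      if (sup %in% iris) {
        anc <- nearest_retained_ancestor(sup, c(seen, iri))
        if (!is.na(anc)) {
          out <- anc
          break
        }
      } else if (sup == IRI_OWL_THING && thing_needed) {
        out <- sup
        break
      }
    }
    nra_memo[[iri]] <- out
    out
  }

  # Candidate parent lists in listed order, after filtering/substitution.
  # Each candidate records the originally listed superclass for reporting.
  candidates <- lapply(retained, function(iri) {
    t <- terms[[iri]]
    out_par <- character()
    out_orig <- character()
    for (sup in t$superclass_iris) {
      resolved <- if (is_retained(sup)) {
        sup
      } else if (sup %in% iris) { # present but hidden (deprecated)
        nearest_retained_ancestor(sup)
      } else if (sup == IRI_OWL_THING && thing_needed) {
        sup
      } else {
        NA_character_ # ghost reference: dropped
      }
      if (!is.na(resolved) && resolved != iri) {
        out_par <- c(out_par, resolved)
        out_orig <- c(out_orig, sup)
      }
    }
    list(parents = out_par, listed = out_orig)
  })
  names(candidates) <- retained

  all_iris <- c(retained, if (thing_needed && !(IRI_OWL_THING %in% retained)) IRI_OWL_THING)
  parent <- stats::setNames(rep(NA_character_, length(all_iris)), all_iris)

  closes_cycle <- function(child, cand) {
    p <- cand
    while (!is.na(p)) {
      if (p == child) return(TRUE)
      p <- parent[[p]]
    }
    FALSE
  }

  dropped_child <- character()
  dropped_parent <- character()
  for (iri in retained) { # source order
    cand <- candidates[[iri]]
    chosen <- NA_character_
    for (j in seq_along(cand$parents)) {
      p <- cand$parents[j]
      if (is.na(chosen)) {
        if (!closes_cycle(iri, p)) {
          chosen <- p
          parent[[iri]] <- p
        } else {
          warning("cycle among superclasses of ", iri,
                  ": candidate ", p, " skipped", call. = FALSE)
          dropped_child <- c(dropped_child, iri)
          dropped_parent <- c(dropped_parent, cand$listed[j])
        }
      } else {
        dropped_child <- c(dropped_child, iri)
        dropped_parent <- c(dropped_parent, cand$listed[j])
      }
    }
  }

  labels <- vapply(all_iris, function(i) {
    if (i %in% iris) {
      l <- terms[[i]]$label
      if (is.na(l)) sub("^.*[/#]", "", i) else l
    } else if (i == IRI_OWL_THING) "Thing" else sub("^.*[/#]", "", i)
  }, "")
  nodes <- data.frame(
    iri = all_iris,
    prefix = extract_prefix(all_iris),
    label = labels,
    definition = vapply(all_iris, function(i) {
      if (i %in% iris) terms[[i]]$definition else NA_character_
    }, ""),
    deprecated = vapply(all_iris, function(i) {
      if (i %in% iris) terms[[i]]$deprecated else FALSE
    }, TRUE),
    parent = unname(parent),
    depth = NA_integer_,
    pinned = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  nodes$synonyms <- lapply(all_iris, function(i) {
    if (i %in% iris) terms[[i]]$synonyms else character()
  })

  g <- new_ontology_graph(
    nodes,
    dropped_edges = data.frame(
      child = dropped_child, dropped_parent = dropped_parent,
      stringsAsFactors = FALSE
    ),
    source_identifier = raw$source_identifier
  )
  compute_depths(g)
}

#' Assign depth strata to every node
#'
#' Depth is the edge count from a node to its root: roots sit at stratum 0 and
#' each child is one stratum below its parent.  The forest invariant (single
#' parent, no cycles) guarantees termination.
#'
#' @param graph An `ontology_graph`.
#' @return The graph with `nodes$depth` filled in.
#' @export
compute_depths <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  nodes <- graph$nodes
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$iri)
  depth <- rep(NA_integer_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(depth[i])) next
    chain <- integer()
    j <- i
    while (is.na(depth[j])) {
      chain <- c(chain, j)
      p <- nodes$parent[j]
      if (is.na(p)) {
        depth[j] <- 0L
        break
      }
      j <- idx[[p]]
    }
    # unwind the chain
    for (k in rev(seq_along(chain))) {
      jj <- chain[k]
      if (is.na(depth[jj])) {
        depth[jj] <- depth[idx[[nodes$parent[jj]]]] + 1L
      }
    }
  }
  graph$nodes$depth <- depth
  graph
}

#' Prune a graph to an upper depth band
#'
#' Retains exactly the nodes whose depth is at most `max_depth`, mirroring the
#' "render from the top down to this node depth" display option for large
#' ontologies.  The forest invariant is preserved because every retained
#' non-root's parent is shallower and therefore also retained.
#'
#' @param graph An `ontology_graph` with depths computed.
#' @param max_depth Non-negative integer depth cap.
#' @return The pruned `ontology_graph`.
#' @export
prune_depth <- function(graph, max_depth) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (length(max_depth) != 1 || is.na(max_depth) || max_depth < 0) {
    stop("max_depth must be a single non-negative integer")
  }
  keep <- graph$nodes$depth <= max_depth
  nodes <- graph$nodes[keep, , drop = FALSE]
  row.names(nodes) <- NULL
  new_ontology_graph(nodes, graph$dropped_edges, graph$source_identifier)
}
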