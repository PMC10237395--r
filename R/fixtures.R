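# Deterministic synthetic ontologies.
#
# Generates multi-prefix OBO-style test ontologies (OBO PURL IRIs,
# rdfs:label, synonym annotations, deprecation flags, ordered multiple
# superclass axioms) and writes them as RDF/XML, so every stage of the
# pipeline is testable offline.  The same spec always yields byte-identical
# OWL output: all randomness flows through the package's portable LCG.
# Deliberately unrealistic in places: labels and synonyms are generated
# strings, definitions are boilerplate, and deprecated terms are always
# leaves (which is what the default deprecation filter assumes anyway).

FIXTURE_PREFIX_POOL <- c(
  "OBI", "PATO", "GO", "CL", "CHEBI", "UBERON", "PR", "SO", "IAO", "ENVO",
  "DOID", "HP", "FOODON", "AGRO", "UO", "ECO", "PO", "TO", "VO", "IDO"
)

#' Specification of a synthetic ontology fixture
#'
#' @param n_terms Number of generated classes (excluding an attached
#'   scaffold), at least 1.
#' @param n_prefixes Number of distinct OBO-style prefixes drawn from a fixed
#'   pool, emulating term reuse across ontologies.
#' @param branching_mean Mean number of children per node of the previous
#'   level during root-down growth.
#' @param multi_parent_fraction Fraction of terms receiving a second
#'   superclass axiom (serialized after the first); the exact count
#'   `round(fraction * n_terms)` is selected deterministically.
#' @param deprecated_fraction Fraction of terms flagged `owl:deprecated`
#'   (always leaves); exact count by construction.
#' @param synonym_fraction Fraction of terms carrying synonym annotations.
#' @param seed Integer seed; same spec, same bytes.
#' @param scaffold Optional scaffold to hang the generated ontology beneath:
#'   the list returned by [scaffold_fixture()] (or a bare `raw_term_set`).
#'   Scaffold leaves become the attachment points of the generated levels.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_terms, n_prefixes = 3, branching_mean = 3,
                         multi_parent_fraction = 0, deprecated_fraction = 0,
                         synonym_fraction = 0.2, seed = 1, scaffold = NULL) {
  stopifnot(
    n_terms >= 1,
    n_prefixes >= 1, n_prefixes <= length(FIXTURE_PREFIX_POOL),
    multi_parent_fraction >= 0, multi_parent_fraction <= 1,
    deprecated_fraction >= 0, deprecated_fraction <= 1,
    synonym_fraction >= 0, synonym_fraction <= 1
  )
  if (branching_mean <= 0) stop("infeasible spec: branching_mean must be positive")
  structure(
    list(
      n_terms = as.integer(n_terms), n_prefixes = as.integer(n_prefixes),
      branching_mean = branching_mean,
      multi_parent_fraction = multi_parent_fraction,
      deprecated_fraction = deprecated_fraction,
      synonym_fraction = synonym_fraction,
      seed = as.integer(seed), scaffold = scaffold
    ),
    class = "fixture_spec"
  )
}

# Deterministic selection of k items: rank by LCG key, take the k smallest.
lcg_pick <- function(state, pool, k) {
  if (k <= 0 || length(pool) == 0) return(list(picked = pool[0], state = state))
  r <- lcg_runif(state, length(pool))
  list(picked = pool[order(r$u)][seq_len(min(k, length(pool)))], state = r$state)
}

#' Generate a synthetic OBO-style ontology
#'
#' Grows a forest root-down level by level (each level's size is the previous
#' level's size times `branching_mean`), distributes terms over prefixes with
#' subtree clustering (a child keeps its parent's prefix with probability
#' 0.8), injects second superclass axioms, deprecation flags and synonyms at
#' the exact configured counts, and serializes everything as RDF/XML.
#'
#' @param spec A [fixture_spec()].
#' @param path Output OWL path; a tempfile by default.
#' @return List with `raw` (the `raw_term_set` as constructed, no re-parse)
#'   and `path` (the written RDF/XML file).
#' @export
generate_ontology <- function(spec, path = tempfile(fileext = ".owl")) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_terms
  state <- derive_seed(spec$seed, "ontoscape-fixture-generator")
  prefixes <- FIXTURE_PREFIX_POOL[seq_len(spec$n_prefixes)]

  scaffold_terms <- list()
  if (!is.null(spec$scaffold)) {
    sc <- if (inherits(spec$scaffold, "raw_term_set")) spec$scaffold else spec$scaffold$raw
    stopifnot(inherits(sc, "raw_term_set"))
    scaffold_terms <- sc$terms
  }

  iri_of <- function(pfx, i) {
    sprintf("http://purl.obolibrary.org/obo/%s_%07d", pfx, 1000000L + i)
  }

  term_prefix <- character(n)
  term_parent <- rep(NA_character_, n) # first superclass
  term_depth <- integer(n)
  term_iri <- character(n)

  # attachment points: scaffold leaves if a scaffold is given, else term 1
  # becomes the single root of the generated tree
  if (length(scaffold_terms)) {
    sc_iris <- names(scaffold_terms)
    sc_parents <- unlist(lapply(scaffold_terms, function(t) t$superclass_iris[1]))
    sc_leaves <- setdiff(sc_iris, sc_parents)
    sc_depth <- vapply(sc_iris, function(ii) {
      d <- 0L
      while (length(scaffold_terms[[ii]]$superclass_iris)) {
        ii <- scaffold_terms[[ii]]$superclass_iris[1]
        if (is.null(scaffold_terms[[ii]])) break
        d <- d + 1L
      }
      d
    }, 0L)
    level_iris <- sc_leaves
    level_depths <- sc_depth[sc_leaves]
    next_i <- 1L
  } else {
    term_prefix[1] <- prefixes[1]
    term_iri[1] <- iri_of(prefixes[1], 1L)
    term_depth[1] <- 0L
    level_iris <- term_iri[1]
    level_depths <- 0L
    next_i <- 2L
  }
  prefix_of_iri <- stats::setNames(term_prefix[seq_len(next_i - 1L)],
                                   term_iri[seq_len(next_i - 1L)])
  depth_of_iri <- stats::setNames(level_depths, level_iris)
  if (length(scaffold_terms)) {
    prefix_of_iri <- stats::setNames(
      extract_prefix(names(scaffold_terms)), names(scaffold_terms)
    )
  }

  by_level <- list(level_iris)
  while (next_i <= n) {
    remaining <- n - next_i + 1L
    size <- min(remaining, max(1L, as.integer(round(length(level_iris) * spec$branching_mean))))
    new_iris <- character(size)
    for (k in seq_len(size)) {
      i <- next_i
      r <- lcg_runif(state, 2)
      state <- r$state
      parent <- level_iris[floor(r$u[1] * length(level_iris)) + 1L]
      keep_pfx <- r$u[2] < 0.8 || length(prefixes) == 1
      ppfx <- prefix_of_iri[[parent]]
      if (is.null(ppfx) || is.na(ppfx) || !(ppfx %in% prefixes)) ppfx <- prefixes[1]
      if (keep_pfx) {
        pfx <- ppfx
      } else {
        r2 <- lcg_runif(state, 1)
        state <- r2$state
        others <- setdiff(prefixes, ppfx)
        pfx <- others[floor(r2$u * length(others)) + 1L]
      }
      term_prefix[i] <- pfx
      term_iri[i] <- iri_of(pfx, i)
      term_parent[i] <- parent
      pd <- depth_of_iri[[parent]]
      term_depth[i] <- pd + 1L
      prefix_of_iri[[term_iri[i]]] <- pfx
      depth_of_iri[[term_iri[i]]] <- term_depth[i]
      new_iris[k] <- term_iri[i]
      next_i <- next_i + 1L
    }
    level_iris <- new_iris
    by_level <- c(by_level, list(new_iris))
  }

  children_count <- base::table(term_parent[!is.na(term_parent)])
  is_leaf <- !(term_iri %in% names(children_count))

  # second superclass axioms: exact count, deterministic selection
  k_mp <- as.integer(round(spec$multi_parent_fraction * n))
  all_idx <- seq_len(n)
  eligible_mp <- all_idx[vapply(all_idx, function(i) {
    if (is.na(term_parent[i])) return(FALSE)
    any(term_depth[seq_len(n)] < term_depth[i] & term_iri != term_parent[i])
  }, TRUE)]
  if (k_mp > length(eligible_mp)) {
    stop("infeasible spec: multi_parent_fraction requires ", k_mp,
         " eligible terms but only ", length(eligible_mp), " exist")
  }
  sel <- lcg_pick(state, eligible_mp, k_mp)
  state <- sel$state
  second_parent <- rep(NA_character_, n)
  for (i in sel$picked) {
    cands <- term_iri[term_depth < term_depth[i] & term_iri != term_parent[i]]
    cands <- cands[nzchar(cands)]
    if (length(scaffold_terms)) cands <- c(cands, setdiff(names(scaffold_terms), term_parent[i]))
    r <- lcg_runif(state, 1)
    state <- r$state
    second_parent[i] <- sort(cands)[floor(r$u * length(cands)) + 1L]
  }

  # deprecated terms: exact count among leaves
  k_dep <- as.integer(round(spec$deprecated_fraction * n))
  leaf_idx <- all_idx[is_leaf]
  if (k_dep > length(leaf_idx)) {
    stop("infeasible spec: deprecated_fraction requires ", k_dep,
         " leaves but only ", length(leaf_idx), " exist")
  }
  sel <- lcg_pick(state, leaf_idx, k_dep)
  state <- sel$state
  deprecated <- all_idx %in% sel$picked

  # synonyms
  k_syn <- as.integer(round(spec$synonym_fraction * n))
  sel <- lcg_pick(state, all_idx, k_syn)
  state <- sel$state
  has_syn <- all_idx %in% sel$picked

  terms <- vector("list", n)
  for (i in all_idx) {
    supers <- c(term_parent[i], second_parent[i])
    supers <- supers[!is.na(supers)]
    terms[[i]] <- new_raw_term(
      iri = term_iri[i],
      label = sprintf("%s term %d", tolower(term_prefix[i]), i),
      synonyms = if (has_syn[i]) sprintf("synonym %d-%s", i, c("a", "b")) else character(),
      definition = sprintf("Synthetic class %d of prefix %s.", i, term_prefix[i]),
      deprecated = deprecated[i],
      superclass_iris = supers
    )
  }
  all_terms <- c(scaffold_terms, terms)
  raw <- new_raw_term_set(all_terms, source_identifier = path, format = "rdfxml")
  write_owl_rdfxml(raw, path)
  list(raw = raw, path = path)
}

# Deterministic RDF/XML serialization of a raw_term_set.
write_owl_rdfxml <- function(raw, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
    "         xmlns:obo=\"http://purl.obolibrary.org/obo/\"",
    "         xmlns:oboInOwl=\"http://www.geneontology.org/formats/oboInOwl#\">"
  )
  for (t in raw$terms) {
    lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\">", esc(t$iri)))
    if (!is.na(t$label)) {
      lines <- c(lines, sprintf("    <rdfs:label xml:lang=\"en\">%s</rdfs:label>", esc(t$label)))
    }
    for (s in t$superclass_iris) {
      lines <- c(lines, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", esc(s)))
    }
    for (s in t$synonyms) {
      lines <- c(lines, sprintf(
        "    <oboInOwl:hasExactSynonym>%s</oboInOwl:hasExactSynonym>", esc(s)
      ))
    }
    if (!is.na(t$definition)) {
      lines <- c(lines, sprintf(
        "    <obo:IAO_0000115>%s</obo:IAO_0000115>", esc(t$definition)
      ))
    }
    if (t$deprecated) {
      lines <- c(lines, paste0(
        "    <owl:deprecated rdf:datatype=\"http://www.w3.org/2001/XMLSchema#boolean\">",
        "true</owl:deprecated>"
      ))
    }
    lines <- c(lines, "  </owl:Class>")
  }
  lines <- c(lines, "</rdf:RDF>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Synthetic 34-term upper-ontology scaffold with pinned coordinates
#'
#' A two-pole upper scaffold in the style of a small upper-level ontology:
#' one branch below the root holds continuant-like terms, the other holds
#' occurrent-like terms.  It uses this package's own synthetic `UBO` IRIs and
#' labels (it is not a copy of any published upper ontology) and ships a
#' matching `pin_config` placing the two poles on opposite sides of the root,
#' every pin lying exactly on its depth stratum for the default
#' `tier_spacing` of 100.
#'
#' @return List with `raw` (a 34-term `raw_term_set`) and `pins`
#'   (a `pin_config` covering all 34 terms).
#' @export
scaffold_fixture <- function() {
  def <- list(
    # id, label, parent id (0 = root)
    list(1, "entity", 0),
    list(2, "continuant", 1), list(3, "occurrent", 1),
    # continuant pole
    list(4, "independent continuant", 2),
    list(5, "specifically dependent continuant", 2),
    list(6, "generically dependent continuant", 2),
    list(7, "spatial region", 2),
    list(8, "material entity", 4), list(9, "immaterial entity", 4),
    list(10, "quality", 5), list(11, "realizable entity", 5),
    list(12, "zero-dimensional spatial region", 7),
    list(13, "one-dimensional spatial region", 7),
    list(14, "two-dimensional spatial region", 7),
    list(15, "three-dimensional spatial region", 7),
    list(16, "object", 8), list(17, "fiat object part", 8),
    list(18, "object aggregate", 8),
    list(19, "site", 9), list(20, "continuant fiat boundary", 9),
    list(21, "role", 11), list(22, "disposition", 11),
    list(23, "relational quality", 10),
    list(24, "function", 22),
    list(25, "zero-dimensional fiat boundary", 20),
    list(26, "one-dimensional fiat boundary", 20),
    list(27, "two-dimensional fiat boundary", 20),
    # occurrent pole
    list(28, "process", 3), list(29, "process boundary", 3),
    list(30, "temporal region", 3), list(31, "spatiotemporal region", 3),
    list(32, "history", 28),
    list(33, "zero-dimensional temporal region", 30),
    list(34, "one-dimensional temporal region", 30)
  )
  iri_of <- function(id) sprintf("http://purl.obolibrary.org/obo/UBO_%07d", id)
  parent_id <- vapply(def, function(d) d[[3]], 0)
  ids <- vapply(def, function(d) d[[1]], 0)
  labels <- vapply(def, function(d) d[[2]], "")

  depth <- integer(length(ids))
  for (k in seq_along(ids)) {
    d <- 0L
    p <- parent_id[k]
    while (p != 0) {
      d <- d + 1L
      p <- parent_id[match(p, ids)]
    }
    depth[k] <- d
  }
  pole <- integer(length(ids)) # 0 root, -1 continuant side, +1 occurrent side
  for (k in seq_along(ids)) {
    if (ids[k] == 1) next
    p <- k
    while (parent_id[p] != 1) p <- match(parent_id[p], ids)
    pole[k] <- if (ids[p] == 2) -1L else 1L
  }

  terms <- lapply(seq_along(ids), function(k) {
    new_raw_term(
      iri = iri_of(ids[k]),
      label = labels[k],
      definition = sprintf("Synthetic upper-scaffold class '%s'.", labels[k]),
      superclass_iris = if (parent_id[k] == 0) character() else iri_of(parent_id[k])
    )
  })
  raw <- new_raw_term_set(terms, source_identifier = "ontoscape:scaffold", format = "rdfxml")

  tier <- 100
  entries <- list()
  for (d in sort(unique(depth))) {
    for (s in c(-1L, 0L, 1L)) {
      grp <- which(depth == d & pole == s)
      if (!length(grp)) next
      m <- length(grp)
      for (j in seq_along(grp)) {
        k <- grp[j]
        x <- if (s == 0L) 0 else s * (140 + 50 * (d - 1))
        z <- (j - (m + 1) / 2) * 70
        entries[[iri_of(ids[k])]] <- c(x, -d * tier, z)
      }
    }
  }
  list(raw = raw, pins = pin_config(entries))
}
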