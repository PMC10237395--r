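# Forest construction: first-listed-parent rule, standalone roots,
# deprecation filter, depths, depth pruning, cycle handling.

test_that("first listed superclass becomes the single parent; others are recorded as dropped", {
  a <- obo("OBI", 1); b <- obo("OBI", 2); c <- obo("OBI", 3)
  raw <- mk_set(
    mk_term(a, label = "A"), mk_term(b, label = "B"),
    mk_term(c, supers = c(a, b), label = "C")
  )
  g <- build_graph(raw)
  expect_identical(g$nodes$parent[g$nodes$iri == c], a)
  expect_identical(g$dropped_edges$child, c)
  expect_identical(g$dropped_edges$dropped_parent, b)
})

test_that("terms without a named superclass are standalone roots; owl:Thing is not standalone", {
  thing <- "http://www.w3.org/2002/07/owl#Thing"
  raw <- mk_set(
    mk_term(obo("OBI", 1), label = "standalone"),
    mk_term(obo("OBI", 2), supers = thing, label = "under thing")
  )
  g <- build_graph(raw)
  expect_true(obo("OBI", 1) %in% g$standalone_roots)
  expect_true(thing %in% g$nodes$iri) # materialized because referenced
  expect_false(thing %in% g$standalone_roots)
  expect_setequal(g$roots, c(obo("OBI", 1), thing))
})

test_that("owl:Thing is omitted when nothing declares or references it", {
  raw <- mk_set(mk_term(obo("OBI", 1)), mk_term(obo("OBI", 2), supers = obo("OBI", 1)))
  g <- build_graph(raw)
  expect_false("http://www.w3.org/2002/07/owl#Thing" %in% g$nodes$iri)
})

test_that("ghost superclass references are dropped", {
  raw <- mk_set(mk_term(obo("OBI", 1), supers = obo("OBI", 999)))
  g <- build_graph(raw)
  expect_identical(g$roots, obo("OBI", 1))
})

test_that("depths follow the parent chain: roots 0, child = parent + 1", {
  r <- obo("GO", 1); a <- obo("GO", 2); b <- obo("GO", 3); c <- obo("GO", 4)
  raw <- mk_set(
    mk_term(r), mk_term(a, supers = r), mk_term(b, supers = a),
    mk_term(c, supers = b), mk_term(obo("GO", 5)) # second root
  )
  g <- build_graph(raw)
  d <- stats::setNames(g$nodes$depth, g$nodes$iri)
  expect_identical(unname(d[c(r, a, b, c)]), 0:3)
  expect_identical(unname(d[obo("GO", 5)]), 0L)
})

test_that("hide_deprecated removes deprecated terms and re-parents survivors", {
  # deprecated leaves: exact count arithmetic
  raw <- generate_ontology(fixture_spec(
    n_terms = 10, deprecated_fraction = 0.2, seed = 4
  ))$raw
  g_hide <- build_graph(raw, hide_deprecated = TRUE)
  g_show <- build_graph(raw, hide_deprecated = FALSE)
  expect_identical(nrow(g_hide$nodes), 8L)
  expect_identical(nrow(g_show$nodes), 10L)

  # deprecated internal node: child re-parents to nearest retained ancestor
  r <- obo("OBI", 1); mid <- obo("OBI", 2); leaf <- obo("OBI", 3)
  raw2 <- mk_set(
    mk_term(r), mk_term(mid, supers = r, deprecated = TRUE),
    mk_term(leaf, supers = mid)
  )
  g2 <- build_graph(raw2, hide_deprecated = TRUE)
  expect_false(mid %in% g2$nodes$iri)
  expect_identical(g2$nodes$parent[g2$nodes$iri == leaf], r)

  # hide_deprecated = FALSE is the identity w.r.t. deprecated nodes
  expect_true(mid %in% build_graph(raw2, hide_deprecated = FALSE)$nodes$iri)
})

test_that("superclass cycles break deterministically into standalone roots, never crash", {
  a <- obo("OBI", 1); b <- obo("OBI", 2)
  raw <- mk_set(mk_term(a, supers = b), mk_term(b, supers = a))
  expect_warning(g <- build_graph(raw), "cycle")
  # processed in source order: a takes parent b; b's only candidate closes a
  # cycle, so b becomes a standalone root
  expect_identical(g$nodes$parent[g$nodes$iri == a], b)
  expect_true(is.na(g$nodes$parent[g$nodes$iri == b]))
  expect_true(b %in% g$standalone_roots)
})

test_that("forest invariant holds on generated ontologies: |edges| = |nodes| - |roots|, no cycles", {
  for (seed in 1:5) {
    raw <- generate_ontology(fixture_spec(
      n_terms = 80, n_prefixes = 4, multi_parent_fraction = 0.25,
      deprecated_fraction = 0.1, seed = seed
    ))$raw
    g <- build_graph(raw)
    n_edges <- sum(!is.na(g$nodes$parent))
    expect_identical(n_edges, nrow(g$nodes) - length(g$roots))
    # every parent chain terminates at a root
    idx <- stats::setNames(seq_len(nrow(g$nodes)), g$nodes$iri)
    for (i in seq_len(nrow(g$nodes))) {
      seen <- 0L
      j <- i
      while (!is.na(g$nodes$parent[j])) {
        j <- idx[[g$nodes$parent[j]]]
        seen <- seen + 1L
        expect_lt(seen, nrow(g$nodes) + 1L)
      }
    }
  }
})

test_that("chosen parents equal the brute-force first-listed-surviving-superclass oracle", {
  for (seed in 1:10) {
    raw <- generate_ontology(fixture_spec(
      n_terms = 50, n_prefixes = 3, multi_parent_fraction = 0.3, seed = seed
    ))$raw
    g <- build_graph(raw, hide_deprecated = FALSE)
    present <- names(raw$terms)
    for (iri in present) {
      oracle <- NA_character_
      for (s in raw$terms[[iri]]$superclass_iris) {
        if (s %in% present) { oracle <- s; break }
      }
      expect_identical(g$nodes$parent[g$nodes$iri == iri], oracle)
    }
  }
})

test_that("depth pruning keeps exactly the upper strata and preserves the forest", {
  # chain of depths 0..3: cap at 1 keeps 2 nodes
  r <- obo("GO", 1); chain <- c(r, obo("GO", 2), obo("GO", 3), obo("GO", 4))
  raw <- do.call(mk_set, lapply(seq_along(chain), function(i) {
    mk_term(chain[i], supers = if (i > 1) chain[i - 1] else character())
  }))
  g <- build_graph(raw)
  expect_identical(nrow(prune_depth(g, 1)$nodes), 2L)
  # identity when the cap exceeds the max depth
  expect_identical(prune_depth(g, 10)$nodes, g$nodes)

  # balanced binary tree of depth 3 (15 nodes): cap 2 keeps 1 + 2 + 4 = 7
  bt <- build_graph(binary_tree_set(3))
  expect_identical(nrow(bt$nodes), 15L)
  pruned <- prune_depth(bt, 2)
  expect_identical(nrow(pruned$nodes), 7L)
  expect_identical(sum(!is.na(pruned$nodes$parent)), 7L - length(pruned$roots))

  expect_error(prune_depth(g, -1), "non-negative")
})
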