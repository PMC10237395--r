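# Layout engine: seed derivation, spawn offsets, stratification, pins,
# determinism, tidy trees, vertical slices, stability.

test_that("derive_seed is pure, IRI-sensitive and master-seed-sensitive", {
  iris <- vapply(1:200, function(i) obo("GO", i), "")
  s1 <- vapply(iris, function(i) derive_seed(42, i), 0)
  s2 <- vapply(iris, function(i) derive_seed(42, i), 0)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L) # distinct across the fixture IRIs
  s3 <- vapply(iris, function(i) derive_seed(43, i), 0)
  expect_true(all(s1 != s3)) # master seed change moves every stream
  expect_true(all(s1 >= 1 & s1 <= 2^31 - 2))
})

test_that("spawn_position is bounded, deterministic, and separates siblings", {
  p <- c(10, -5)
  for (seed in c(1, 999, 123456)) {
    s1 <- spawn_position(p, seed, 30)
    s2 <- spawn_position(p, seed, 30)
    expect_identical(s1, s2)
    off <- sqrt(sum((s1 - p)^2))
    expect_gt(off, 0)
    expect_lte(off, 30)
  }
  # 1000 sibling spawns from the same parent never coincide
  seeds <- vapply(1:1000, function(i) derive_seed(7, obo("CL", i)), 0)
  pts <- t(vapply(seeds, function(s) spawn_position(c(0, 0), s, 30), c(0, 0)))
  expect_identical(anyDuplicated(round(pts, 12)), 0L)
})

test_that("every node sits exactly on its depth stratum: y = -depth * tier_spacing", {
  res <- generate_ontology(fixture_spec(n_terms = 120, n_prefixes = 4, seed = 5))
  g <- build_graph(parse_ontology(res$path))
  for (tier in c(100, 40)) {
    co <- layout(g, params = layout_params(tier_spacing = tier))
    expect_identical(max(abs(co[g$nodes$iri, "y"] + g$nodes$depth * tier)), 0)
  }
})

test_that("a single pinned root is returned exactly at its pin", {
  raw <- mk_set(mk_term(obo("BFO", 1), label = "entity"))
  g <- build_graph(raw)
  pins <- pin_config(list("BFO:0000001" = c(12.5, 0, -7.25)))
  co <- layout(g, pins = pins)
  expect_identical(unname(co[1, ]), c(12.5, 0, -7.25))
})

test_that("a chain stratifies tier by tier", {
  r <- obo("GO", 1); a <- obo("GO", 2); b <- obo("GO", 3)
  raw <- mk_set(mk_term(r), mk_term(a, supers = r), mk_term(b, supers = a))
  co <- layout(build_graph(raw))
  expect_identical(unname(co[c(r, a, b), "y"]), c(0, -100, -200))
})

test_that("layout is bitwise deterministic and seed-sensitive", {
  res <- generate_ontology(fixture_spec(n_terms = 200, n_prefixes = 4, seed = 8))
  g <- build_graph(parse_ontology(res$path))
  co1 <- layout(g, params = layout_params(master_seed = 5))
  co2 <- layout(g, params = layout_params(master_seed = 5))
  expect_identical(co1, co2) # zero maximum difference, bit for bit
  co3 <- layout(g, params = layout_params(master_seed = 6))
  expect_false(isTRUE(all.equal(co1, co3)))
})

test_that("pinned scaffold coordinates are reproduced exactly beneath a hung ontology", {
  sc <- scaffold_fixture()
  res <- generate_ontology(fixture_spec(n_terms = 300, n_prefixes = 4, seed = 2,
                                        scaffold = sc))
  g <- build_graph(res$raw)
  co <- layout(g, pins = sc$pins)
  for (iri in names(sc$pins$entries)) {
    expect_identical(unname(co[iri, ]), as.numeric(sc$pins$entries[[iri]]))
  }
})

test_that("unresolved pin entries are ignored with a warning", {
  raw <- mk_set(mk_term(obo("OBI", 1)))
  pins <- pin_config(list("XX:0009999" = c(1, 0, 1)))
  expect_warning(co <- layout(build_graph(raw), pins = pins), "unresolved pin")
  expect_identical(unname(co[1, ]), c(0, 0, 0))
})

test_that("tidy_tree_2d centers parents over IRI-ordered, non-overlapping children", {
  # single node at the origin
  single <- build_graph(mk_set(mk_term(obo("GO", 1))))
  uv <- tidy_tree_2d(single)
  expect_identical(unname(uv[1, ]), c(0, 0))

  # parent with two leaves: parent u midway between children
  p <- obo("GO", 1); l1 <- obo("GO", 2); l2 <- obo("GO", 3)
  g <- build_graph(mk_set(mk_term(p), mk_term(l1, supers = p), mk_term(l2, supers = p)))
  uv <- tidy_tree_2d(g)
  expect_equal(uv[p, "u"], (uv[l1, "u"] + uv[l2, "u"]) / 2)
  expect_false(uv[l1, "u"] == uv[l2, "u"])

  # full binary tree of depth 2: leaf u strictly increasing in IRI order
  bt <- build_graph(binary_tree_set(2))
  uvb <- tidy_tree_2d(bt)
  leaves <- sort(bt$nodes$iri[bt$nodes$depth == 2])
  expect_true(all(diff(uvb[leaves, "u"]) > 0))
  expect_identical(unname(uvb[leaves, "v"]), rep(-200, 4))
})

test_that("slice layout puts deep branches into their anchors' vertical half-planes", {
  # anchor at depth 1 with a 3-node chain below: all coplanar with the
  # vertical plane through the anchor's azimuth
  r <- obo("OBI", 1); a1 <- obo("OBI", 2); a2 <- obo("OBI", 3)
  c1 <- obo("OBI", 4); c2 <- obo("OBI", 5); c3 <- obo("OBI", 6)
  d1 <- obo("OBI", 7)
  raw <- mk_set(
    mk_term(r), mk_term(a1, supers = r), mk_term(a2, supers = r),
    mk_term(c1, supers = a1), mk_term(c2, supers = c1), mk_term(c3, supers = c2),
    mk_term(d1, supers = a2)
  )
  g <- build_graph(raw)
  co <- slice_layout(g, scaffold_depth = 1)

  in_plane <- function(anchor, members) {
    az <- atan2(co[anchor, "z"], co[anchor, "x"])
    d <- c(cos(az), sin(az))
    normal <- c(-d[2], d[1]) # horizontal normal of the vertical plane
    offs <- cbind(co[members, "x"] - co[anchor, "x"], co[members, "z"] - co[anchor, "z"])
    max(abs(offs %*% normal))
  }
  expect_lt(in_plane(a1, c(c1, c2, c3)), 1e-9)
  expect_lt(in_plane(a2, d1), 1e-9)

  # distinct anchors at distinct azimuths get distinct planes
  az1 <- atan2(co[a1, "z"], co[a1, "x"])
  az2 <- atan2(co[a2, "z"], co[a2, "x"])
  expect_gt(abs(az1 - az2), 1e-6)

  # stratification survives slicing
  expect_identical(max(abs(co[g$nodes$iri, "y"] + g$nodes$depth * 100)), 0)

  # no slices needed: identical to the plain 3D layout
  shallow <- prune_depth(g, 1)
  expect_identical(slice_layout(shallow, scaffold_depth = 3), layout(shallow))
})

test_that("adding a deep leaf leaves pins untouched and barely moves the top strata", {
  sc <- scaffold_fixture()
  res <- generate_ontology(fixture_spec(n_terms = 150, seed = 6))
  raw <- res$raw
  g1 <- build_graph(raw)
  deep <- g1$nodes$iri[which.max(g1$nodes$depth)]
  leaf <- mk_term(obo("OBI", 9999999), supers = deep, label = "extra leaf")
  raw2 <- ontoscape:::new_raw_term_set(
    c(raw$terms, list(leaf)), raw$source_identifier, raw$format
  )
  g2 <- build_graph(raw2)
  co1 <- layout(g1)
  co2 <- layout(g2)
  d1 <- g1$nodes$iri[g1$nodes$depth == 1]
  expect_lt(max(abs(co1[d1, , drop = FALSE] - co2[d1, , drop = FALSE])), 30)

  # and with the pinned scaffold, pins cannot move at all
  res_p <- generate_ontology(fixture_spec(n_terms = 150, seed = 6, scaffold = sc))
  gp1 <- build_graph(res_p$raw)
  deep_p <- gp1$nodes$iri[which.max(gp1$nodes$depth)]
  raw_p2 <- ontoscape:::new_raw_term_set(
    c(res_p$raw$terms, list(mk_term(obo("OBI", 9999998), supers = deep_p))),
    res_p$raw$source_identifier, res_p$raw$format
  )
  gp2 <- build_graph(raw_p2)
  cp1 <- layout(gp1, pins = sc$pins)
  cp2 <- layout(gp2, pins = sc$pins)
  pin_iris <- names(sc$pins$entries)
  expect_identical(cp1[pin_iris, ], cp2[pin_iris, ])
})
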