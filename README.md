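# ontoscape

Deterministic 3D visualization of OWL ontology class hierarchies.

Application ontologies in the OBO Foundry style reuse terms from many source
ontologies — qualities from PATO, cell types from CL, processes from GO —
under a small upper-level backbone.  `ontoscape` makes that term reuse
visible: it parses an OWL file (RDF/XML or Turtle), extracts the named-class
subsumption (`rdfs:subClassOf`) hierarchy, and computes a 3D layout in which

- every hierarchy depth *n* = 0, 1, 2, … occupies its own horizontal plane at
  `y = -n * tier_spacing`, exactly (a stratified "mountain" of terms);
- upper-ontology scaffold nodes can be **pinned** to fixed coordinates, so
  every ontology grows beneath the same recognizable constellation;
- child generations are inserted tier by tier, each settling before the next
  spawns near its parents — which avoids the "ostracised" nodes that random
  initialization strands far from their neighbors;
- every node is colored by its ontology prefix (`OBI`, `PATO`, `GO`, …), with
  a legend of per-prefix term counts;
- the whole layout is a **pure function** of (graph, pins, parameters):
  repeated runs are bitwise identical, and a structure-hash cache reuses
  coordinates whenever the class structure is unchanged.

Classes with multiple superclasses keep only the **first listed** one; OWL
axioms other than subsumption are not rendered.  Deprecated terms are hidden
by default.  Scenes serialize to JSON and export to a self-contained
interactive HTML viewer (orbit navigation, click-to-highlight, label and
wireframe toggles).  A deterministic generator of synthetic multi-prefix
OBO-style ontologies makes the whole pipeline testable offline.

## Worked example

```r
library(ontoscape)

# a deterministic synthetic ontology: 300 terms over 5 prefixes,
# hung beneath the packaged 34-term two-pole upper scaffold
sc  <- scaffold_fixture()
owl <- generate_ontology(fixture_spec(n_terms = 300, n_prefixes = 5,
                                      seed = 2, scaffold = sc))

raw <- parse_ontology(owl$path)
raw
#> <raw_term_set> 334 classes from /tmp/.../file...owl (rdfxml)

g <- build_graph(raw)          # first-listed-parent forest, depths assigned
g
#> <ontology_graph> 334 nodes, 333 edges, 1 root(s) (1 standalone), max depth 8

co <- layout(g, pins = sc$pins)
head(co, 3)
#>                                              x    y   z
#> http://purl.obolibrary.org/obo/UBO_0000001    0    0  0
#> http://purl.obolibrary.org/obo/UBO_0000002 -140 -100  0
#> http://purl.obolibrary.org/obo/UBO_0000003  140 -100  0

max(abs(co[, "y"] + g$nodes$depth * 100))   # stratification is exact
#> [1] 0
max(abs(co - layout(g, pins = sc$pins)))    # and the layout is deterministic
#> [1] 0

scene <- build_scene(g, co, pins = sc$pins)
scene
#> <scene> 334 nodes, 333 edges, 6 legend prefixes (hash ...)
write_scene(scene, "scene.json")
render_html(scene, "scene.html")            # standalone interactive viewer

search_terms("continuant", g)[, c("label", "prefix", "depth")]  # synonym-aware search
term_context("UBO:0000002", g)              # parent/children/definition + OntoBee/OLS links
```

The numbers above mean: the 34 scaffold terms sit exactly at their pinned
coordinates (the two poles at x = ∓140 on the first stratum), all 334 nodes
lie exactly on their depth planes, and a second run reproduces every
coordinate bit for bit.

The same pipeline is scriptable from a shell:

```sh
exec/ontoscape layout --source my_ontology.owl --scene-out scene.json \
    --cache-dir .cache --html-out scene.html --summary
exec/ontoscape search --source my_ontology.owl --query dog
```

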