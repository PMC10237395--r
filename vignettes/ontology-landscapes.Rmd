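---
title: "Depth-stratified 3D landscapes of ontology class hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-stratified 3D landscapes of ontology class hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoscape)
```

## The problem

Application ontologies in the OBO Foundry style reuse terms from many source
ontologies: an investigation ontology imports qualities from PATO, cell types
from CL, processes from GO, all hanging under a small upper-level backbone.
In textual class browsers that interconnectedness is invisible — you must
read prefixes out of identifiers.  `ontoscape` renders the class hierarchy as
a 3D landscape in which every source ontology has one color, every hierarchy
depth occupies its own horizontal plane, and the upper-level backbone sits at
fixed, recognizable coordinates, so the question "which ontologies does this
project reuse, and where?" becomes visual.

Only the named-class subsumption hierarchy is drawn.  Restrictions, object
properties, individuals and classes that appear solely inside axioms are out
of scope, as are reasoning and import-closure resolution: the file is taken
as given.

## From OWL to a forest

`parse_ontology()` reads RDF/XML (via `xml2`) or Turtle (via an internal
reader, since no installed RDF toolkit parses Turtle) and produces one record
per declared `owl:Class`: label (first `en`-tagged wins), OBO-style synonyms
(deduplicated in exact > narrow > broad > related priority), textual
definition, the `owl:deprecated` flag, and — crucially — the superclass IRIs
*in serialization order*.  RDF graphs are unordered in most toolkits, but the
hierarchy rule below is order-dependent, so the parser works from the byte
stream itself; reparsing the same bytes always yields a field-for-field
identical result.

`build_graph()` collapses multiple inheritance to a forest: each class keeps
the **first listed** superclass that survives filtering.  A listed superclass
survives if it exists among retained terms and accepting it does not close a
cycle; terms are processed in source order, and a term whose candidates are
exhausted becomes a standalone root.  OWL permits cycles the display cannot,
so this deterministic tie-break — next listed candidate, then standalone —
was the design choice; a warning is logged, never a crash.  Suppressed
multi-inheritance edges are retained in a side table so reports can state how
many were dropped (they are never rendered).  `owl:Thing` is materialized
only when declared or referenced; top-level classes with no stated path to it
are flagged as *standalone roots* and drawn disconnected, which is exactly
how a reference ontology that ships an unconnected `owl:Thing` should look.

Deprecated terms are hidden by default.  When a hidden term has
non-deprecated descendants, they re-parent to the nearest retained ancestor
along the first-listed chain rather than vanish — hiding is meant to reduce
clutter, not to disconnect surviving branches.  `hide_deprecated = FALSE` is
the exact identity on deprecated nodes.

Depth is the edge count to the root: `compute_depths()` assigns the stratum
index, and `prune_depth()` implements the "render from the top down to this
depth" cap for very large ontologies.

## The layout model

The vertical axis is y, "up" toward the roots — the concrete axis and sign
were open choices; y-up matches most scene-graph conventions.  Every node
sits **exactly** at `y = -depth * tier_spacing`: stratification is enforced
by construction, not by a force, so it holds to the last bit.

Planar positions come from a force simulation with three ingredients: a
spring pulling each node toward its parent's planar position
(`spring_k = 0.05`), inverse-square repulsion among active unpinned nodes
with a cutoff of `3 * tier_spacing` (`repulsion_k = 1500`), and velocity
damping (`damping = 0.85`).  The cutoff keeps the cost near-linear via a
uniform spatial grid, which is what makes ontologies of several thousand
terms tractable on one CPU.  With these constants a pair of siblings settles
roughly 35–40 units apart under a shared parent — comfortable next to the
30-unit spawn radius and the 100-unit tier spacing.  All constants are
user-configurable through `layout_params()`; the defaults are this package's
own calibration, chosen for legible spacing at the default tier height.

Random initialization is what traps "ostracised" nodes far from their
neighbors, so insertion is **generational**: roots first (pinned ones at
their configured coordinates, the rest on a circle of radius `tier_spacing`
ordered by IRI — any deterministic rule works, and IRI order is
serialization-independent), then each deeper generation spawns within
`jitter_radius = 30` units of its parent and the simulation relaxes until the
largest displacement falls below `settle_epsilon = 0.1` units or 300
iterations elapse.  Earlier generations are not frozen — lower tiers must be
able to pull apart — but cool exponentially, a factor 0.3 per elapsed
generation, which is the compromise between "settle each generation" and
"let the mountain spread".  `layout(insertion = "all_at_once")` implements
the random-scatter control with the same total iteration budget; the test
suite checks that the generational schedule yields a median child–parent
planar distance no larger than the control's on 500-node ontologies — on our
fixtures the margin is roughly an order of magnitude.

Determinism is the central contract: all pseudo-randomness flows from
`derive_seed(master_seed, iri)` — an FNV-1a hash of the IRI mixed with the
master seed, feeding a Park–Miller generator implemented in plain double
arithmetic — so a layout is a pure function of (graph, pins, parameters),
bitwise identical across runs, sessions and platforms, and independent of
R's own RNG state.  If the force integration ever produced a non-finite
coordinate the step size is halved and the generation retried, up to five
times; with the default constants this path is unreachable.

**Pinned nodes never move.**  A `pin_config()` maps IRIs or CURIEs to fixed
coordinates; the shipped `scaffold_fixture()` provides a synthetic 34-term
two-pole upper scaffold (continuant-like and occurrent-like branches on
opposite sides of the root) whose pins all lie exactly on their strata.  It
deliberately uses its own `UBO` IRIs: it emulates the *shape* of a small
upper-level ontology without copying any published one.  A pin whose y
conflicts with its node's stratum is kept as configured, with a warning —
pin fidelity is the stronger promise of the two.

The hybrid slice view (`slice_layout()`) keeps the upper scaffold in 3D and
draws each deeper subtree as a classical tidy tree inside the vertical
half-plane through its anchor's azimuth: siblings in IRI order occupy
non-overlapping intervals, parents centered over children, `jitter_radius`
as the leaf spacing.  No reference prescribes the in-plane algorithm or
spacing; the layered tidy tree is this package's choice.  Pins below the
scaffold depth are not honored in slice mode — those nodes belong to their
subtree's plane.

## Styling and the legend

A packaged lookup table maps ~40 common OBO Foundry prefixes to colors, with
upper-scaffold prefixes bright yellow so the backbone stays visible when
zoomed out; unknown prefixes get a deterministic hue-hashed fallback (hue
collisions are possible and accepted — the table is user-replaceable).
Edges take the **child** node's color, so an imported subtree reads as one
colored block up to its attachment point; whether the original tool colors
by child or parent is unstated, and this was the choice made here.  Edge
thickness tapers `max(1, 6 - parent_depth)`; wireframe mode forces 1 unit
everywhere except scaffold edges.  Top-level nodes get radius 8 versus base
3.  The legend lists each prefix with its color and term count, descending,
ties alphabetical; counts always partition the node set.

## Scenes and the coordinate cache

`build_scene()` assembles positioned, styled nodes and edges plus the legend
into a JSON-serializable scene (schema-versioned; unknown versions are
rejected on read, and doubles are written with 17 significant digits so the
round trip is lossless).  The cache key is `structure_hash()` — a digest of
the sorted IRI and edge lists *only*, so relabeling or restyling reuses
cached coordinates while any structural edit invalidates them.  The cache
also keys on a digest of the layout parameters and pins, which is stricter
than a structure-only key: coordinates computed under different physics
should never be served silently.  Because layout is deterministic, a cache
hit is indistinguishable from a fresh computation, and the tests assert
exact equality.  `render_html()` writes a single self-contained HTML viewer
(orbit navigation with a fixed vertical up-vector — free flight is what
causes the disorienting "rollercoaster" effect — click-to-highlight in red,
label and wireframe toggles); it performs no layout and embeds the scene
verbatim.

## What the synthetic fixtures do and do not show

`generate_ontology()` grows deterministic multi-prefix OBO-style ontologies:
level-by-level growth at a configurable mean branching factor, prefix
inheritance with probability 0.8 (so imported-looking blocks form, as in
real application ontologies), exact counts of second-superclass axioms,
deprecated leaves and synonyms, byte-identical output per seed.  The study
sizes used by the test suite are 100–1,000 terms for the determinism sweep,
500 for the insertion comparison, 1,000 under the pinned scaffold, and
4,000 for the scale check — the size class of a medium agronomy or
epidemiology ontology.  What the generator does **not** emulate: real label
text, non-leaf deprecated terms (its deprecated terms are always leaves),
anonymous-class axioms, equivalence axioms, or the heavy-tailed branching of
real taxonomies.  Passing tests therefore demonstrate the pipeline's
contracts (ordering, determinism, stratification, pin fidelity, exact
filtering counts) — not that any particular real ontology will look good;
for that, load one.

## Degenerate inputs and numerical notes

A single pinned root returns its pin exactly (nothing moves).  Coincident
nodes in the simulation are separated by a deterministic index-based nudge
rather than a random one.  An ontology with zero classes is an explicit
error, never an empty success.  Cycle-only ontologies degrade to standalone
roots with warnings.  Scene files that fail validation name the offending
field and never yield partial scenes; corrupt cache entries are recomputed
and overwritten with a warning.

All four OBO synonym scopes are indexed for search — the narrowest reading
would index only exact synonyms, but the colloquial-lookup use case argues
for all scopes, and that is the documented choice.
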