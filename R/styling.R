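# Styling: prefix colors, node sizes, edge thicknesses, legend.
#
# Consistent per-prefix coloring is what makes term reuse visible: every node
# from one source ontology gets the same color in a scene and across runs.
# The shipped table covers the common OBO Foundry prefixes; unknown prefixes
# fall back to a deterministic hue-hashing rule, so coloring is total.

#' Prefix-to-color lookup table
#'
#' Loads the packaged OBO Foundry palette (or a user table of the same JSON
#' form, `{"PREFIX": "#RRGGBB", ...}`).  Scaffold / upper-ontology prefixes
#' are mapped to bright yellow so the backbone stands out when zoomed out;
#' additional prefixes can be declared as scaffold via `scaffold_prefixes`.
#'
#' @param path Optional path to a JSON color table; default: packaged palette.
#' @param scaffold_prefixes Prefixes to force to the scaffold yellow.
#' @return A `color_table` with `entries` (named list of RGB triples) and a
#'   deterministic `fallback_rule`.
#' @export
color_table <- function(path = NULL, scaffold_prefixes = character()) {
  if (is.null(path)) {
    path <- system.file("extdata", "obo_colors.json", package = "ontoscape")
  }
  hexes <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(hexes, hex_to_rgb)
  for (p in scaffold_prefixes) entries[[toupper(p)]] <- c(255, 255, 0)
  structure(
    list(entries = entries, fallback_rule = fallback_color),
    class = "color_table"
  )
}

hex_to_rgb <- function(hex) {
  as.integer(grDevices::col2rgb(hex)[, 1])
}

rgb_to_hex <- function(rgb) {
  grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
}

# Deterministic fallback: hash the prefix to a hue, fixed saturation/value.
# Distinct prefixes can collide (360 hue buckets); collisions are accepted --
# the table is user-replaceable when that matters.
fallback_color <- function(prefix) {
  h <- fnv1a32(toupper(prefix)) %% 360
  as.integer(grDevices::col2rgb(grDevices::hsv(h / 360, 0.55, 0.85))[, 1])
}

#' Color for an ontology prefix
#'
#' Table lookup with a pure deterministic fallback for unknown prefixes.
#'
#' @param prefix Ontology prefix string (case-insensitive for table entries).
#' @param table A `color_table`.
#' @return Integer RGB triple in 0..255.
#' @export
color_for_prefix <- function(prefix, table = color_table()) {
  stopifnot(inherits(table, "color_table"))
  e <- table$entries[[toupper(prefix)]]
  if (!is.null(e)) return(as.integer(e))
  table$fallback_rule(prefix)
}

#' Edge thickness by hierarchy depth
#'
#' Default mode renders heavier edges near the top of the hierarchy:
#' `max(1, t0 - depth_of_parent)`, so edges below depth `t0 - 1` have just
#' 1 unit of thickness.  Wireframe mode forces 1 unit everywhere except
#' scaffold (top-level ontology) edges, which keep their default thickness.
#' Monotone non-increasing in depth.
#'
#' @param depth_of_parent Non-negative integer depth of the edge's parent end.
#' @param wireframe Logical.
#' @param scaffold Logical: is this an upper-scaffold edge?
#' @param t0 Thickness at depth 0 in default mode.
#' @return Numeric thickness in scene units.
#' @export
edge_thickness <- function(depth_of_parent, wireframe = FALSE,
                           scaffold = FALSE, t0 = 6) {
  stopifnot(all(depth_of_parent >= 0))
  default_t <- pmax(1, t0 - depth_of_parent)
  ifelse(wireframe & !scaffold, 1, default_t)
}

#' Node size by role
#'
#' Top-level (scaffold / depth-0) terms get a larger radius so they remain
#' discernible when zoomed far out; all other nodes share the base size.
#'
#' @param depth Non-negative integer depth (unused by the default rule but
#'   part of the contract so alternative rules can depend on it).
#' @param is_top_level Logical.
#' @param s_top,s_base Radii in scene units.
#' @return Numeric radius.
#' @export
node_size <- function(depth, is_top_level, s_top = 8, s_base = 3) {
  stopifnot(all(depth >= 0))
  ifelse(is_top_level, s_top, s_base)
}

#' Per-prefix legend of a graph
#'
#' One entry per distinct prefix carrying its color and term count, ordered by
#' descending count with alphabetical tie-break.  Counts partition the node
#' set: they sum to the number of nodes.
#'
#' @param graph An `ontology_graph`.
#' @param table A `color_table`.
#' @return Data frame with columns `prefix`, `color` (hex), `term_count`.
#' @export
build_legend <- function(graph, table = color_table()) {
  stopifnot(inherits(graph, "ontology_graph"))
  counts <- base::table(graph$nodes$prefix)
  df <- data.frame(
    prefix = names(counts),
    term_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  df$color <- vapply(df$prefix, function(p) rgb_to_hex(color_for_prefix(p, table)), "")
  df <- df[order(-df$term_count, df$prefix), c("prefix", "color", "term_count")]
  row.names(df) <- NULL
  df
}
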