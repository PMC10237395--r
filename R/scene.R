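# Scene assembly, serialization, and the structure-hash coordinate cache.
#
# A scene is the fully positioned and styled node/edge set plus the legend —
# everything a viewer needs, with no layout left to do.  Scenes and cache
# records are JSON with a schema_version; the cache is keyed by a hash of the
# class structure alone (IRIs + edges), so relabeling or restyling an
# ontology reuses the cached coordinates, while any structural edit
# invalidates them.

md5_of_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(charToRaw(enc2utf8(x)), f)
  unname(tools::md5sum(f))
}

#' Structure hash of an ontology graph
#'
#' Hex digest over the sorted node IRI list and the sorted (child, parent)
#' edge list only.  Labels, synonyms, colors and coordinates are excluded, so
#' two loadings with identical class structure — the condition under which
#' the visual structure must be identical — hash equal, and any structural
#' edit (adding or removing a node or edge) changes the digest.
#'
#' @param graph An `ontology_graph`.
#' @return Hex digest string.
#' @export
structure_hash <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  edges <- graph_edges(graph)
  edge_str <- sort(paste(edges$child, edges$parent, sep = " -> "))
  md5_of_string(paste(
    c("nodes:", sort(graph$nodes$iri), "edges:", edge_str),
    collapse = "\n"
  ))
}

params_digest <- function(params, pins = NULL) {
  p <- unclass(params)
  pj <- jsonlite::toJSON(p[order(names(p))], auto_unbox = TRUE, digits = I(17))
  sj <- if (is.null(pins) || length(pins$entries) == 0) {
    "{}"
  } else {
    as.character(jsonlite::toJSON(pins$entries[order(names(pins$entries))], digits = I(17)))
  }
  md5_of_string(paste0(pj, "|", sj))
}

#' Assemble a styled scene
#'
#' Combines an `ontology_graph`, its coordinates, and a color table into a
#' serializable scene: styled nodes (position, per-prefix color, size),
#' styled edges (thickness by parent depth; each edge takes its child node's
#' color), legend, and provenance metadata.
#'
#' @param graph An `ontology_graph` with depths computed.
#' @param coords A `coordinates` matrix from [layout()] or [slice_layout()].
#' @param table A `color_table`.
#' @param params The `layout_params` used (recorded in the metadata digest).
#' @param pins The `pin_config` used, if any.
#' @param wireframe Use wireframe edge thicknesses.
#' @return A `scene` object.
#' @export
build_scene <- function(graph, coords, table = color_table(),
                        params = layout_params(), pins = NULL,
                        wireframe = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  nodes <- graph$nodes
  stopifnot(all(nodes$iri %in% rownames(coords)))
  coords <- coords[nodes$iri, , drop = FALSE]

  pin_map <- resolve_pins(pins, graph)
  pinned <- nodes$iri %in% names(pin_map)
  top_level <- pinned | nodes$depth == 0

  node_tbl <- data.frame(
    iri = nodes$iri,
    label = nodes$label,
    prefix = nodes$prefix,
    depth = nodes$depth,
    deprecated = nodes$deprecated,
    x = unname(coords[, "x"]),
    y = unname(coords[, "y"]),
    z = unname(coords[, "z"]),
    color = vapply(nodes$prefix, function(p) rgb_to_hex(color_for_prefix(p, table)), "",
                   USE.NAMES = FALSE),
    size = node_size(nodes$depth, top_level),
    pinned = pinned,
    stringsAsFactors = FALSE
  )

  edges <- graph_edges(graph)
  if (nrow(edges)) {
    pidx <- match(edges$parent, nodes$iri)
    cidx <- match(edges$child, nodes$iri)
    scaffold_edge <- pinned[cidx] & pinned[pidx]
    edge_tbl <- data.frame(
      child_iri = edges$child,
      parent_iri = edges$parent,
      thickness = edge_thickness(nodes$depth[pidx], wireframe, scaffold_edge),
      color = node_tbl$color[cidx],
      stringsAsFactors = FALSE
    )
  } else {
    edge_tbl <- data.frame(
      child_iri = character(), parent_iri = character(),
      thickness = numeric(), color = character(), stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      schema_version = SCENE_SCHEMA_VERSION,
      nodes = node_tbl,
      edges = edge_tbl,
      legend = build_legend(graph, table),
      meta = list(
        source_identifier = graph$source_identifier,
        structure_hash = structure_hash(graph),
        params_digest = params_digest(params, pins),
        creation_timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        tool_version = as.character(utils::packageVersion("ontoscape"))
      )
    ),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d nodes, %d edges, %d legend prefixes (hash %s)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$legend),
    substr(x$meta$structure_hash, 1, 8)
  ))
  invisible(x)
}

#' Write / read a scene as JSON
#'
#' Lossless round trip: positions and thicknesses are serialized at full
#' double precision, and `read_scene(write_scene(s))` equals `s`
#' field-for-field.  Files with a missing or unknown `schema_version`, or
#' with missing required fields, are rejected with a validation error naming
#' the offence — never returned as a partial scene.
#'
#' @param scene A `scene`.
#' @param path File path.
#' @return `read_scene` returns a `scene`; `write_scene` returns `path`
#'   invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene"))
  jsonlite::write_json(
    unclass(scene), path,
    dataframe = "columns", auto_unbox = TRUE, digits = I(17), null = "null",
    na = "null"
  )
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("scene validation error: unreadable JSON (", conditionMessage(e), ")")
  )
  if (is.null(obj$schema_version)) stop("scene validation error: missing field 'schema_version'")
  if (!identical(obj$schema_version, SCENE_SCHEMA_VERSION)) {
    stop("scene validation error: unknown schema_version '", obj$schema_version, "'")
  }
  for (f in c("nodes", "edges", "legend", "meta")) {
    if (is.null(obj[[f]])) stop("scene validation error: missing field '", f, "'")
  }
  node_cols <- c("iri", "label", "prefix", "depth", "deprecated", "x", "y", "z",
                 "color", "size", "pinned")
  for (cn in node_cols) {
    if (is.null(obj$nodes[[cn]])) stop("scene validation error: missing node field '", cn, "'")
  }
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  for (cn in c("x", "y", "z", "size")) nodes[[cn]] <- as.numeric(nodes[[cn]])
  nodes$depth <- as.integer(nodes$depth)
  nodes$deprecated <- as.logical(nodes$deprecated)
  nodes$pinned <- as.logical(nodes$pinned)
  edges <- if (length(obj$edges) == 0 || is.null(obj$edges$child_iri)) {
    data.frame(
      child_iri = character(), parent_iri = character(),
      thickness = numeric(), color = character(), stringsAsFactors = FALSE
    )
  } else {
    e <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
    e$thickness <- as.numeric(e$thickness)
    e
  }
  legend <- as.data.frame(obj$legend, stringsAsFactors = FALSE)
  legend$term_count <- as.integer(legend$term_count)
  bad <- setdiff(c(edges$child_iri, edges$parent_iri), nodes$iri)
  if (length(bad)) {
    stop("scene validation error: edge endpoint(s) absent from nodes: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(
      schema_version = obj$schema_version,
      nodes = nodes, edges = edges, legend = legend,
      meta = obj$meta
    ),
    class = "scene"
  )
}

#' Cache-aware layout
#'
#' Looks for a cache record keyed by the graph's [structure_hash()] in
#' `cache_dir`; on a hit whose `params_digest` also matches, the cached
#' coordinates are returned without running the simulation (by layout
#' determinism they equal a fresh computation exactly).  On a miss the layout
#' is computed and stored.  Corrupt cache entries are treated as misses and
#' overwritten with a warning.
#'
#' @inheritParams layout
#' @param cache_dir Directory for cache records (created if absent); `NULL`
#'   disables caching.
#' @param verbose Log hit/miss to standard error.
#' @return A `coordinates` matrix, with attribute `cache` = "hit" or "miss".
#' @export
load_or_layout <- function(graph, pins = NULL, params = layout_params(),
                           cache_dir = NULL, verbose = FALSE) {
  if (is.null(cache_dir)) {
    out <- layout(graph, pins, params)
    attr(out, "cache") <- "disabled"
    return(out)
  }
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  shash <- structure_hash(graph)
  pdig <- params_digest(params, pins)
  rec_path <- file.path(cache_dir, paste0(shash, ".json"))

  if (file.exists(rec_path)) {
    rec <- tryCatch(jsonlite::read_json(rec_path, simplifyVector = TRUE),
                    error = function(e) NULL)
    cc <- rec$coordinates
    ok <- !is.null(rec) &&
      identical(rec$schema_version, SCENE_SCHEMA_VERSION) &&
      identical(rec$structure_hash, shash) &&
      identical(rec$params_digest, pdig) &&
      !is.null(cc) && all(c("iri", "x", "y", "z") %in% names(cc)) &&
      setequal(cc$iri, graph$nodes$iri)
    if (ok) {
      if (verbose) message("layout cache hit: ", shash)
      ord <- match(graph$nodes$iri, cc$iri)
      out <- cbind(x = cc$x[ord], y = cc$y[ord], z = cc$z[ord])
      rownames(out) <- graph$nodes$iri
      out <- structure(out, class = c("coordinates", class(out)))
      attr(out, "cache") <- "hit"
      return(out)
    }
    if (!is.null(rec) && !identical(rec$params_digest, pdig)) {
      if (verbose) message("layout cache miss (parameters changed): ", shash)
    } else {
      warning("corrupt cache entry ", rec_path, "; recomputing", call. = FALSE)
    }
  } else if (verbose) {
    message("layout cache miss: ", shash)
  }

  out <- layout(graph, pins, params)
  jsonlite::write_json(
    list(
      schema_version = SCENE_SCHEMA_VERSION,
      structure_hash = shash,
      params_digest = pdig,
      coordinates = list(
        iri = rownames(out),
        x = unname(out[, "x"]), y = unname(out[, "y"]), z = unname(out[, "z"])
      )
    ),
    rec_path,
    auto_unbox = TRUE, digits = I(17)
  )
  attr(out, "cache") <- "miss"
  out
}
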