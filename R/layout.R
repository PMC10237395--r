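# Deterministic depth-stratified 3D layout.
#
# The vertical axis is y with "up" toward the roots: every node sits exactly
# at y = -depth * tier_spacing, so each hierarchy depth occupies its own
# horizontal plane.  Planar (x, z) positions come from a force relaxation
# with generation-by-generation insertion: roots are placed first (pinned
# scaffold nodes at their configured coordinates, the rest on a circle),
# then each deeper generation spawns near its parents and the simulation
# settles before the next generation is added.  Earlier generations stay
# mobile but cool exponentially, letting lower tiers spread without
# destroying the settled upper structure.

#' Layout parameters
#'
#' All constants steering the force simulation, with documented defaults.
#'
#' @param tier_spacing Scene units of vertical separation per depth stratum.
#' @param repulsion_k Inverse-square repulsion constant.
#' @param spring_k Attraction constant toward the parent's planar position.
#' @param damping Velocity decay per step, strictly in (0, 1).
#' @param max_iter_per_generation Iteration cap for each insertion generation.
#' @param settle_epsilon A generation is settled once the largest per-step
#'   displacement falls below this (scene units).
#' @param jitter_radius Children spawn within this planar radius of their
#'   parent.
#' @param master_seed Integer seed mixed with each term's IRI hash; the whole
#'   layout is a pure function of (graph, pins, params).
#' @return A `layout_params` list.
#' @export
layout_params <- function(tier_spacing = 100, repulsion_k = 1500,
                          spring_k = 0.05, damping = 0.85,
                          max_iter_per_generation = 300,
                          settle_epsilon = 0.1, jitter_radius = 30,
                          master_seed = 1) {
  stopifnot(
    tier_spacing > 0, repulsion_k > 0, spring_k > 0,
    damping > 0, damping < 1, max_iter_per_generation >= 1,
    settle_epsilon > 0, jitter_radius > 0, is.finite(master_seed)
  )
  structure(
    list(
      tier_spacing = tier_spacing, repulsion_k = repulsion_k,
      spring_k = spring_k, damping = damping,
      max_iter_per_generation = as.integer(max_iter_per_generation),
      settle_epsilon = settle_epsilon, jitter_radius = jitter_radius,
      master_seed = master_seed
    ),
    class = "layout_params"
  )
}

#' Pin configuration: fixed coordinates for scaffold terms
#'
#' Upper-ontology scaffold nodes can be pinned to fixed 3D coordinates so the
#' force simulation grows every ontology beneath the same recognizable
#' constellation.  Entries are named by IRI or OBO-style CURIE
#' (`PREFIX:localid`, expanded against the OBO PURL namespace at resolution
#' time); entries that resolve to no loaded term are ignored with a warning.
#'
#' @param entries Named list: identifier to numeric `c(x, y, z)`.
#' @return A `pin_config`.
#' @export
pin_config <- function(entries = list()) {
  if (length(entries)) {
    stopifnot(!is.null(names(entries)), all(nzchar(names(entries))))
    ok <- vapply(entries, function(e) length(e) == 3 && all(is.finite(e)), TRUE)
    if (!all(ok)) stop("pin entries must be finite length-3 coordinate triples")
  }
  structure(list(entries = entries), class = "pin_config")
}

#' Read / write a pin configuration as JSON
#'
#' The on-disk form is a JSON object mapping CURIE or IRI to an `[x, y, z]`
#' array.
#'
#' @param path File path.
#' @param pins A `pin_config` (for writing).
#' @return `read_pin_config` returns a `pin_config`.
#' @export
read_pin_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pin_config(lapply(obj, as.numeric))
}

#' @rdname read_pin_config
#' @export
write_pin_config <- function(pins, path) {
  stopifnot(inherits(pins, "pin_config"))
  jsonlite::write_json(pins$entries, path, auto_unbox = FALSE, digits = I(17))
  invisible(path)
}

curie_to_obo_iri <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z][A-Za-z0-9]*):([A-Za-z0-9_]+)$", id))[[1]]
  if (length(m) == 3) paste0("http://purl.obolibrary.org/obo/", m[2], "_", m[3]) else id
}

# Resolve pin identifiers against a graph; returns named list iri -> c(x,y,z).
resolve_pins <- function(pins, graph) {
  if (is.null(pins) || length(pins$entries) == 0) return(list())
  out <- list()
  unresolved <- character()
  for (id in names(pins$entries)) {
    iri <- if (id %in% graph$nodes$iri) id else curie_to_obo_iri(id)
    if (iri %in% graph$nodes$iri) {
      out[[iri]] <- as.numeric(pins$entries[[id]])
    } else {
      unresolved <- c(unresolved, id)
    }
  }
  if (length(unresolved)) {
    warning("ignoring unresolved pin entries: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  out
}

#' Seed-determined spawn offset for a child node
#'
#' Children enter the simulation near their parent: at the parent's planar
#' position plus a pseudo-random offset whose magnitude lies in
#' `(0, jitter_radius]`.  The offset is a pure function of the node seed, so
#' the spawn — like everything downstream — is reproducible, and it is never
#' exactly zero, so siblings never coincide.
#'
#' @param parent_xz Numeric length-2 planar position of the parent.
#' @param node_seed Integer seed, typically from [derive_seed()].
#' @param jitter_radius Positive spawn radius.
#' @return Numeric length-2 planar position.
#' @export
spawn_position <- function(parent_xz, node_seed, jitter_radius) {
  stopifnot(length(parent_xz) == 2, jitter_radius > 0)
  u <- lcg_runif(node_seed, 2)$u
  angle <- 2 * pi * u[1]
  r <- jitter_radius * sqrt(max(u[2], 1e-8))
  parent_xz + r * c(cos(angle), sin(angle))
}

# Shared placement of the root stratum + pinned nodes.
# Returns list(x, z, pinned_mask) aligned with graph$nodes rows.
init_positions <- function(graph, pin_map, params) {
  nodes <- graph$nodes
  n <- nrow(nodes)
  x <- numeric(n)
  z <- numeric(n)
  pinned <- nodes$iri %in% names(pin_map)

  for (iri in names(pin_map)) {
    i <- match(iri, nodes$iri)
    p <- pin_map[[iri]]
    x[i] <- p[1]
    z[i] <- p[3]
    expected_y <- -nodes$depth[i] * params$tier_spacing
    if (abs(p[2] - expected_y) > 1e-9) {
      warning("pin for ", iri, " has y = ", p[2], " but stratum y = ",
              expected_y, "; pin value kept", call. = FALSE)
    }
  }

  root_idx <- which(nodes$depth == 0 & !pinned)
  if (length(root_idx)) {
    root_idx <- root_idx[order(nodes$iri[root_idx])]
    m <- length(root_idx)
    if (m == 1) {
      x[root_idx] <- 0
      z[root_idx] <- 0
    } else {
      ang <- 2 * pi * (seq_len(m) - 1) / m
      x[root_idx] <- params$tier_spacing * cos(ang)
      z[root_idx] <- params$tier_spacing * sin(ang)
    }
  }
  list(x = x, z = z, pinned = pinned)
}

relax_with_halving <- function(xz, parent_idx0, active, pinned, temp, params, max_iter) {
  dt <- 1
  for (attempt in 0:5) {
    res <- relax_cpp(
      xz, parent_idx0, active, pinned, temp,
      params$spring_k, params$repulsion_k, 3 * params$tier_spacing,
      params$damping, params$settle_epsilon, as.integer(max_iter), dt
    )
    if (!res$nonfinite) return(res$pos)
    if (attempt == 5) stop("force simulation diverged even after 5 step-size halvings")
    dt <- dt / 2
  }
}

#' Compute the 3D layout of an ontology graph
#'
#' The default, `insertion = "generational"`, reproduces top-down mountain
#' building: the root stratum is placed first, each deeper generation spawns
#' near its parents and the planar force simulation (parent springs,
#' cutoff inverse-square repulsion, velocity damping) settles before the next
#' generation is inserted; previously placed nodes remain mobile with a
#' temperature multiplier of 0.3 per elapsed generation.  Pinned nodes never
#' move.  `insertion = "all_at_once"` instead scatters every node
#' pseudo-randomly at the start and runs the same simulation with the same
#' total iteration budget — it exists as the experimental control
#' demonstrating why generational insertion avoids ostracised nodes, and is
#' not used by the pipeline.
#'
#' Both modes are pure functions of `(graph, pins, params)`: repeated runs
#' give bitwise-identical coordinates.
#'
#' @param graph An `ontology_graph` with depths computed.
#' @param pins Optional `pin_config`.
#' @param params A `layout_params`.
#' @param insertion `"generational"` (default) or `"all_at_once"`.
#' @return A `coordinates` object: numeric matrix with columns x, y, z and
#'   one row per node, rownames = IRIs; `y = -depth * tier_spacing` exactly.
#' @examples
#' owl <- generate_ontology(fixture_spec(n_terms = 40, seed = 3))
#' g <- build_graph(parse_ontology(owl$path))
#' head(layout(g))
#' @export
layout <- function(graph, pins = NULL, params = layout_params(),
                   insertion = c("generational", "all_at_once")) {
  insertion <- match.arg(insertion)
  stopifnot(inherits(graph, "ontology_graph"), inherits(params, "layout_params"))
  nodes <- graph$nodes
  if (nrow(nodes) == 0) stop("cannot lay out an empty graph")
  if (anyNA(nodes$depth)) graph <- compute_depths(graph)
  nodes <- graph$nodes

  pin_map <- resolve_pins(pins, graph)
  init <- init_positions(graph, pin_map, params)
  x <- init$x
  z <- init$z
  pinned <- init$pinned
  parent_idx0 <- match(nodes$parent, nodes$iri) - 1L
  parent_idx0[is.na(parent_idx0)] <- -1L
  max_depth <- max(nodes$depth)

  if (insertion == "generational") {
    if (max_depth >= 1) {
      for (g in seq_len(max_depth)) {
        gen_idx <- which(nodes$depth == g & !pinned)
        for (i in gen_idx) {
          pi <- parent_idx0[i] + 1L
          parent_xz <- if (pi > 0) c(x[pi], z[pi]) else c(0, 0)
          sp <- spawn_position(
            parent_xz, derive_seed(params$master_seed, nodes$iri[i]),
            params$jitter_radius
          )
          x[i] <- sp[1]
          z[i] <- sp[2]
        }
        active <- nodes$depth <= g
        temp <- 0.3^pmax(g - nodes$depth, 0)
        res <- relax_with_halving(
          cbind(x, z), parent_idx0, active, pinned, temp, params,
          params$max_iter_per_generation
        )
        x <- res[, 1]
        z <- res[, 2]
      }
    } else if (any(!pinned)) {
      # single stratum: relax the root circle only
      res <- relax_with_halving(
        cbind(x, z), parent_idx0, rep(TRUE, nrow(nodes)), pinned,
        rep(1, nrow(nodes)), params, params$max_iter_per_generation
      )
      x <- res[, 1]
      z <- res[, 2]
    }
  } else {
    # all-at-once control: scatter unpinned non-root nodes uniformly in a
    # disc of radius 3 * tier_spacing, then one relaxation with the same
    # total iteration budget the generational schedule would get
    scatter_idx <- which(nodes$depth > 0 & !pinned)
    for (i in scatter_idx) {
      u <- lcg_runif(derive_seed(params$master_seed, nodes$iri[i]), 2)$u
      ang <- 2 * pi * u[1]
      r <- 3 * params$tier_spacing * sqrt(u[2])
      x[i] <- r * cos(ang)
      z[i] <- r * sin(ang)
    }
    budget <- params$max_iter_per_generation * max(max_depth, 1)
    res <- relax_with_halving(
      cbind(x, z), parent_idx0, rep(TRUE, nrow(nodes)), pinned,
      rep(1, nrow(nodes)), params, budget
    )
    x <- res[, 1]
    z <- res[, 2]
  }

  y <- -nodes$depth * params$tier_spacing
  for (iri in names(pin_map)) { # pins carry exactly their configured values
    i <- match(iri, nodes$iri)
    x[i] <- pin_map[[iri]][1]
    y[i] <- pin_map[[iri]][2]
    z[i] <- pin_map[[iri]][3]
  }
  coords <- cbind(x = x, y = y, z = z)
  rownames(coords) <- nodes$iri
  structure(coords, class = c("coordinates", class(coords)))
}

#' Tidy 2D layout of a tree fragment
#'
#' Classical layered tidy-tree placement used for the vertical-slice view:
#' the in-plane vertical coordinate is `v = -relative_depth * tier_spacing`;
#' siblings are ordered by IRI and occupy non-overlapping horizontal
#' intervals; each parent is centered over its children.  Deterministic.
#'
#' @param fragment An `ontology_graph` (or compatible node table) that forms a
#'   single tree; the unique depth-minimal node is the fragment root.
#' @param params A `layout_params` (supplies `tier_spacing` and the sibling
#'   spacing, taken as `jitter_radius`).
#' @return Matrix with columns `u`, `v`, rownames = IRIs; root at `(0, 0)`.
#' @export
tidy_tree_2d <- function(fragment, params = layout_params()) {
  nodes <- if (inherits(fragment, "ontology_graph")) fragment$nodes else fragment
  n <- nrow(nodes)
  spacing <- params$jitter_radius
  root_i <- which(nodes$depth == min(nodes$depth))
  if (length(root_i) != 1) stop("fragment must be a single tree")

  kids <- split(seq_len(n), match(nodes$parent, nodes$iri))
  children_of <- function(i) {
    ks <- kids[[as.character(i)]]
    if (is.null(ks)) integer() else ks[order(nodes$iri[ks])]
  }

  width <- numeric(n)
  post <- function(i) {
    ch <- children_of(i)
    if (!length(ch)) {
      width[i] <<- spacing
    } else {
      for (c in ch) post(c)
      width[i] <<- max(spacing, sum(width[ch]))
    }
  }
  post(root_i)

  u <- numeric(n)
  v <- numeric(n)
  place <- function(i, left, rel_depth) {
    ch <- children_of(i)
    v[i] <<- -rel_depth * params$tier_spacing
    if (!length(ch)) {
      u[i] <<- left + width[i] / 2
    } else {
      off <- left
      for (c in ch) {
        place(c, off, rel_depth + 1)
        off <- off + width[c]
      }
      u[i] <<- (u[ch[1]] + u[ch[length(ch)]]) / 2
    }
  }
  place(root_i, -width[root_i] / 2, 0)

  out <- cbind(u = u, v = v)
  rownames(out) <- nodes$iri
  # shift so the fragment root is the origin
  out[, "u"] <- out[, "u"] - out[root_i, "u"]
  out
}

#' Hybrid 3D / vertical-slice layout
#'
#' The upper scaffold (depth at most `scaffold_depth`) is laid out by
#' [layout()] in 3D; every deeper node is assigned to the subtree of its
#' ancestor at `scaffold_depth` and drawn by [tidy_tree_2d()] inside a
#' vertical half-plane anchored at that ancestor, the plane's azimuth being
#' the ancestor's azimuth about the vertical axis through the scene origin.
#' Depth stratification still holds for every node.
#'
#' @inheritParams layout
#' @param scaffold_depth Non-negative integer: deepest stratum drawn in 3D.
#' @return A `coordinates` matrix as for [layout()].
#' @export
slice_layout <- function(graph, pins = NULL, params = layout_params(),
                         scaffold_depth = 1) {
  stopifnot(inherits(graph, "ontology_graph"), scaffold_depth >= 0)
  nodes <- graph$nodes
  if (anyNA(nodes$depth)) {
    graph <- compute_depths(graph)
    nodes <- graph$nodes
  }
  max_depth <- max(nodes$depth)
  if (max_depth <= scaffold_depth) return(layout(graph, pins, params))

  upper <- prune_depth(graph, scaffold_depth)
  upper_pins <- pins
  if (!is.null(pins) && length(pins$entries)) {
    # pins below the scaffold depth are not honored in slice mode: those
    # nodes live in their subtree's 2D plane instead
    keep <- vapply(names(pins$entries), function(id) {
      iri <- if (id %in% upper$nodes$iri) id else curie_to_obo_iri(id)
      iri %in% upper$nodes$iri
    }, TRUE)
    upper_pins <- pin_config(pins$entries[keep])
  }
  upper_coords <- layout(upper, upper_pins, params)

  coords <- matrix(NA_real_, nrow(nodes), 3,
                   dimnames = list(nodes$iri, c("x", "y", "z")))
  coords[rownames(upper_coords), ] <- upper_coords

  # ancestor at scaffold_depth for each deeper node
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$iri)
  anchor_of <- rep(NA_integer_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (nodes$depth[i] <= scaffold_depth) next
    j <- i
    while (nodes$depth[j] > scaffold_depth) j <- idx[[nodes$parent[j]]]
    anchor_of[i] <- j
  }

  for (a in sort(unique(anchor_of[!is.na(anchor_of)]))) {
    members <- c(a, which(anchor_of == a))
    frag <- nodes[members, , drop = FALSE]
    row.names(frag) <- NULL
    uv <- tidy_tree_2d(frag, params)
    ax <- coords[nodes$iri[a], "x"]
    az <- coords[nodes$iri[a], "z"]
    azimuth <- atan2(az, ax)
    if (!is.finite(azimuth)) azimuth <- 0
    dirx <- cos(azimuth)
    dirz <- sin(azimuth)
    for (k in seq_along(members)) {
      i <- members[k]
      if (i == a) next # anchor keeps its 3D position
      coords[nodes$iri[i], "x"] <- ax + uv[k, "u"] * dirx
      coords[nodes$iri[i], "z"] <- az + uv[k, "u"] * dirz
      coords[nodes$iri[i], "y"] <- -nodes$depth[i] * params$tier_spacing
    }
  }
  structure(coords, class = c("coordinates", class(coords)))
}
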