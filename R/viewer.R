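# Standalone HTML viewer export.
#
# Emits one self-contained HTML file: the scene JSON is embedded verbatim in
# a <script type="application/json"> block and a small dependency-free
# canvas renderer draws it with orbit-style navigation (the camera's up
# vector stays aligned with the scene's vertical axis, so a top-down sense
# of "up" is never lost).  The viewer performs no layout: positions, colors,
# sizes and thicknesses are taken from the scene as-is.  Clicking a node
# highlights it in red and shows its label and context.

#' Viewer options
#'
#' @param show_labels Render node labels (default on).
#' @param label_backdrop Render a semi-transparent backdrop box behind each
#'   label for legibility (default on).
#' @param wireframe Start in wireframe mode (thin edges).
#' @return A `viewer_options` list.
#' @export
viewer_options <- function(show_labels = TRUE, label_backdrop = TRUE,
                           wireframe = FALSE) {
  structure(
    list(
      show_labels = isTRUE(show_labels),
      label_backdrop = isTRUE(label_backdrop),
      wireframe = isTRUE(wireframe)
    ),
    class = "viewer_options"
  )
}

#' Export a scene as a standalone interactive HTML file
#'
#' @param scene A `scene` from [build_scene()].
#' @param path Output HTML path.
#' @param options A [viewer_options()].
#' @return `path`, invisibly.
#' @export
render_html <- function(scene, path, options = viewer_options()) {
  stopifnot(inherits(scene, "scene"), inherits(options, "viewer_options"))
  scene_json <- tryCatch(
    as.character(jsonlite::toJSON(
      unclass(scene), dataframe = "rows", auto_unbox = TRUE, digits = I(17),
      na = "null"
    )),
    error = function(e) stop("scene cannot be serialized: ", conditionMessage(e))
  )
  opts_json <- as.character(jsonlite::toJSON(unclass(options), auto_unbox = TRUE))
  html <- viewer_template()
  html <- sub("__SCENE_JSON__", scene_json, html, fixed = TRUE)
  html <- sub("__OPTIONS_JSON__", opts_json, html, fixed = TRUE)
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

viewer_template <- function() {
  paste0('<!DOCTYPE html>
<html>
<head>
<meta charset="utf-8">
<title>ontoscape scene</title>
<style>
 body { margin:0; background:#111; color:#eee; font:13px sans-serif; overflow:hidden; }
 #panel { position:absolute; top:10px; left:10px; background:rgba(0,0,0,0.7);
          padding:8px 12px; border-radius:6px; max-width:340px; }
 #legend { position:absolute; top:10px; right:10px; background:rgba(0,0,0,0.7);
           padding:8px 12px; border-radius:6px; }
 .sw { display:inline-block; width:10px; height:10px; margin-right:6px; }
 label { margin-right: 10px; }
</style>
</head>
<body>
<canvas id="cv"></canvas>
<div id="panel">
  <div>
    <label><input type="checkbox" id="labels"> labels</label>
    <label><input type="checkbox" id="wire"> wireframe</label>
  </div>
  <div id="info">drag to orbit, wheel to zoom, shift-drag to pan, click a node</div>
</div>
<div id="legend"></div>
<script type="application/json" id="scene-data">__SCENE_JSON__</script>
<script type="application/json" id="viewer-options">__OPTIONS_JSON__</script>
<script>
const scene = JSON.parse(document.getElementById("scene-data").textContent);
const opts = JSON.parse(document.getElementById("viewer-options").textContent);
const HIGHLIGHT_COLOR = "red";
const cv = document.getElementById("cv"), ctx = cv.getContext("2d");
let yaw = 0.6, pitch = 0.35, dist = 900, panX = 0, panY = 0, selected = null;
const nodes = scene.nodes, edges = scene.edges;
const byIri = {}; nodes.forEach(n => byIri[n.iri] = n);
let cx = 0, cy = 0, cz = 0;
nodes.forEach(n => { cx += n.x; cy += n.y; cz += n.z; });
cx /= nodes.length; cy /= nodes.length; cz /= nodes.length;
document.getElementById("labels").checked = opts.show_labels;
document.getElementById("wire").checked = opts.wireframe;
function project(n) {
  const x = n.x - cx, y = n.y - cy, z = n.z - cz;
  // orbit: yaw about the vertical (y) axis, then pitch; up stays vertical
  const x1 = x * Math.cos(yaw) + z * Math.sin(yaw);
  const z1 = -x * Math.sin(yaw) + z * Math.cos(yaw);
  const y1 = y * Math.cos(pitch) - z1 * Math.sin(pitch);
  const z2 = y * Math.sin(pitch) + z1 * Math.cos(pitch);
  const s = dist / (dist + z2 + 2 * dist);
  return { sx: cv.width / 2 + (x1 * s) + panX, sy: cv.height / 2 - (y1 * s) + panY, s: s };
}
function draw() {
  cv.width = window.innerWidth; cv.height = window.innerHeight;
  ctx.clearRect(0, 0, cv.width, cv.height);
  const showLabels = document.getElementById("labels").checked;
  const wire = document.getElementById("wire").checked;
  const pos = {};
  nodes.forEach(n => pos[n.iri] = project(n));
  edges.forEach(e => {
    const a = pos[e.child_iri], b = pos[e.parent_iri];
    ctx.strokeStyle = e.color; ctx.globalAlpha = 0.75;
    ctx.lineWidth = Math.max(0.5, (wire ? Math.min(e.thickness, 1) : e.thickness) * a.s);
    ctx.beginPath(); ctx.moveTo(a.sx, a.sy); ctx.lineTo(b.sx, b.sy); ctx.stroke();
  });
  ctx.globalAlpha = 1;
  nodes.forEach(n => {
    const p = pos[n.iri];
    ctx.fillStyle = (selected === n.iri) ? HIGHLIGHT_COLOR : n.color;
    ctx.beginPath(); ctx.arc(p.sx, p.sy, Math.max(1.5, n.size * p.s), 0, 2 * Math.PI);
    ctx.fill();
    if (showLabels && n.size * p.s > 2) {
      if (opts.label_backdrop) {
        ctx.fillStyle = "rgba(0,0,0,0.5)";
        const w = ctx.measureText(n.label).width;
        ctx.fillRect(p.sx + 6, p.sy - 10, w + 4, 13);
      }
      ctx.fillStyle = "#ddd"; ctx.fillText(n.label, p.sx + 8, p.sy);
    }
  });
}
let dragging = false, lx = 0, ly = 0, shift = false;
cv.addEventListener("mousedown", e => { dragging = true; lx = e.clientX; ly = e.clientY; shift = e.shiftKey; });
window.addEventListener("mouseup", () => dragging = false);
window.addEventListener("mousemove", e => {
  if (!dragging) return;
  if (shift) { panX += e.clientX - lx; panY += e.clientY - ly; }
  else {
    yaw += (e.clientX - lx) * 0.01;
    pitch = Math.max(-1.4, Math.min(1.4, pitch + (e.clientY - ly) * 0.01));
  }
  lx = e.clientX; ly = e.clientY; draw();
});
cv.addEventListener("wheel", e => { dist *= (e.deltaY > 0 ? 1.1 : 0.9); draw(); });
cv.addEventListener("click", e => {
  let best = null, bd = 100;
  nodes.forEach(n => {
    const p = project(n);
    const d = Math.hypot(p.sx + panX * 0 - e.clientX, p.sy - e.clientY);
    if (d < bd) { bd = d; best = n; }
  });
  if (best) {
    selected = best.iri;
    const kids = edges.filter(x => x.parent_iri === best.iri).map(x => byIri[x.child_iri].label);
    document.getElementById("info").innerHTML =
      "<b>" + best.label + "</b><br>" + best.iri + "<br>prefix " + best.prefix +
      ", depth " + best.depth + (kids.length ? "<br>children: " + kids.join(", ") : "");
  }
  draw();
});
document.getElementById("labels").addEventListener("change", draw);
document.getElementById("wire").addEventListener("change", draw);
window.addEventListener("resize", draw);
const lg = document.getElementById("legend");
lg.innerHTML = scene.legend.map(l =>
  "<div><span class=\'sw\' style=\'background:" + l.color + "\'></span>" +
  l.prefix + " (" + l.term_count + ")</div>").join("");
draw();
</script>
</body>
</html>')
}
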