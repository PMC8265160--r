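# Deterministic layout and styling for the two linked views: the lineage
# tree (left panel) and the orthographically projected 3D cell cloud (right
# panel).  SVG output is byte-stable for a given scene: all geometry is
# formatted with fixed precision and no run-dependent state enters the file.

#' Default categorical palette and neutral colour
#'
#' Twelve well-separated categorical colours; cells in no selected group are
#' drawn in the neutral light grey.
#' @return Character vector of 12 hex colours.
#' @export
default_palette <- function() {
  c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
    "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78")
}

neutral_colour <- function() "#D3D3D3"

# Sequential colormap used for expression heatmaps and relationship levels.
seq_colormap <- function(x01) {
  stops <- c("#440154", "#443983", "#31688E", "#21918C", "#35B779",
             "#90D743", "#FDE725")
  ramp <- grDevices::colorRamp(stops, space = "rgb")
  rgbm <- ramp(pmin(pmax(x01, 0), 1))
  grDevices::rgb(rgbm[, 1L], rgbm[, 2L], rgbm[, 3L], maxColorValue = 255)
}

#' Assign colours to an ordered list of groups
#'
#' The first `length(palette)` groups receive distinct palette colours;
#' beyond that the palette cycles with a warning.  Stable: the same group
#' order always yields the same map.
#'
#' @param groups named list of character vectors (group name -> member cell
#'   labels), e.g. the `groups` of a `clone_partition`.
#' @param palette ordered colour vector, default [default_palette()].
#' @return List with `cell_colours` (named cell -> colour) and
#'   `group_colours` (named group -> colour).
#' @export
assign_colours <- function(groups, palette = default_palette()) {
  if (!length(groups)) {
    return(list(cell_colours = stats::setNames(character(0), character(0)),
                group_colours = stats::setNames(character(0), character(0))))
  }
  if (length(groups) > length(palette)) {
    warning("more groups (", length(groups), ") than palette colours (",
            length(palette), "); colours will repeat")
  }
  gcol <- palette[((seq_along(groups) - 1L) %% length(palette)) + 1L]
  names(gcol) <- names(groups)
  cells <- unlist(groups, use.names = FALSE)
  ccol <- rep(gcol, lengths(groups))
  names(ccol) <- cells
  list(cell_colours = ccol, group_colours = gcol)
}

#' Map a gene's expression values onto a sequential colour scale
#'
#' Linear map from the `[min, max]` of the gene's values over the given
#' cells to the sequential colormap, with a legend recording the numeric
#' range.  A constant gene yields a single-colour map with a warning.
#'
#' @param expr an `expression_table`.
#' @param gene gene name; unknown names raise an error listing the nearest
#'   autofill matches.
#' @param cells cell labels to map (default: all cells in the table).
#' @return List with `cell_colours` (named cell -> colour) and `legend`
#'   (list: `gene`, `min`, `max`).
#' @export
expression_scale <- function(expr, gene, cells = expr$cells) {
  if (!(gene %in% expr$genes)) {
    near <- utils::head(gene_lookup(expr, substr(gene, 1L, 3L)), 5L)
    if (!length(near)) near <- utils::head(sort(expr$genes), 5L)
    stop("unknown gene '", gene, "'; did you mean: ",
         paste(near, collapse = ", "))
  }
  cells <- intersect(cells, expr$cells)
  v <- expr$values[cells, gene]
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("gene '", gene, "' has constant expression (", fmt_num(rng[1L]),
            ") over the mapped cells; heatmap is degenerate")
    col <- rep(seq_colormap(0.5), length(v))
  } else {
    col <- seq_colormap((v - rng[1L]) / diff(rng))
  }
  list(cell_colours = stats::setNames(col, cells),
       legend = list(gene = gene, min = rng[1L], max = rng[2L]))
}

# --- Overlays ----------------------------------------------------------

#' Scene overlays
#'
#' Exactly one overlay colours a scene: a clone partition, a
#' relationship map, a categorical annotation table, or one gene of an
#' expression table.
#'
#' @param partition a `clone_partition`.
#' @return An overlay object for [scene()].
#' @export
overlay_clones <- function(partition) {
  stopifnot(inherits(partition, "clone_partition"))
  structure(list(kind = "clones", partition = partition), class = "overlay")
}

#' @rdname overlay_clones
#' @param relmap a `relationship_map` from [relationship_levels()].
#' @export
overlay_relationship <- function(relmap) {
  stopifnot(inherits(relmap, "relationship_map"))
  structure(list(kind = "relationship", relmap = relmap), class = "overlay")
}

#' @rdname overlay_clones
#' @param annotations an `annotation_table`.
#' @export
overlay_annotation <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  structure(list(kind = "annotation", annotations = annotations),
            class = "overlay")
}

#' @rdname overlay_clones
#' @param expr an `expression_table`.
#' @param gene gene name to display.
#' @export
overlay_expression <- function(expr, gene) {
  stopifnot(inherits(expr, "expression_table"))
  structure(list(kind = "expression", expr = expr, gene = gene),
            class = "overlay")
}

#' Build a reproducible linked-view scene
#'
#' A scene fixes everything a rendering depends on: the joined dataset, the
#' view state (collapsed/pruned branches), the tree layout mode, at most
#' one colour overlay, the sphere radius of the 3D cells, the palette and
#' the projection angles.  Identical scenes render to byte-identical SVG.
#'
#' @param joined a `joined_dataset` from [join_cells()].
#' @param view a `view_state` (default: empty).
#' @param layout_mode `"cladogram"` (uniform depths) or `"branch_length"`
#'   (x positions are node times).
#' @param overlay `NULL` or one of the `overlay_*()` constructors.
#' @param sphere_radius radius of the 3D cell spheres in pixels
#'   (default 6).
#' @param palette categorical palette.
#' @param azimuth,elevation orthographic projection angles in degrees for
#'   the static 3D panel.
#' @return A `scene` object with a computed `colour_map` (one colour per
#'   cell; neutral where no overlay applies) and `legend` (for expression
#'   overlays).
#' @export
scene <- function(joined, view = view_state(),
                  layout_mode = c("cladogram", "branch_length"),
                  overlay = NULL, sphere_radius = 6,
                  palette = default_palette(),
                  azimuth = 30, elevation = 20) {
  stopifnot(inherits(joined, "joined_dataset"))
  layout_mode <- match.arg(layout_mode)
  if (!is.null(overlay) && !inherits(overlay, "overlay")) {
    stop("overlay must be NULL or built by an overlay_*() constructor")
  }
  stopifnot(sphere_radius > 0)
  all_cells <- leaf_labels(joined$tree)
  cmap <- stats::setNames(rep(neutral_colour(), length(all_cells)), all_cells)
  legend <- NULL
  if (!is.null(overlay)) {
    oc <- switch(overlay$kind,
      clones = assign_colours(overlay$partition$groups, palette)$cell_colours,
      relationship = {
        lv <- overlay$relmap$level
        hi <- max(lv)
        stats::setNames(seq_colormap(if (hi == 0) rep(0.5, length(lv))
                                     else lv / hi), names(lv))
      },
      annotation = {
        ann <- overlay$annotations
        cats <- sort(unique(ann$annotation), method = "radix")
        groups <- lapply(cats, function(a) ann$cell[ann$annotation == a])
        names(groups) <- cats
        assign_colours(groups, palette)$cell_colours
      },
      expression = {
        es <- expression_scale(overlay$expr, overlay$gene,
                               cells = joined$matched)
        legend <- es$legend
        es$cell_colours
      })
    keep <- intersect(names(oc), all_cells)
    cmap[keep] <- oc[keep]
  }
  structure(list(joined = joined, view = view, layout_mode = layout_mode,
                 overlay = overlay, sphere_radius = sphere_radius,
                 palette = palette, azimuth = azimuth, elevation = elevation,
                 colour_map = cmap, legend = legend),
            class = "scene")
}

# --- Tree layout -------------------------------------------------------

#' Lay out a lineage tree for drawing
#'
#' Computes one (x, y) position per displayed node.  Pruned subtrees are
#' absent; a collapsed subtree occupies a single leaf slot carrying its
#' clone size.  In cladogram mode x is the node depth with all leaves
#' flush at the maximum depth; in branch-length mode x is the node's time
#' from the root (falling back to cladogram with a warning when the tree
#' has no branch lengths).  Deterministic for a given (tree, view, mode).
#'
#' @param tree a `lineage_tree`.
#' @param view a `view_state`.
#' @param mode `"cladogram"` or `"branch_length"`.
#' @return A `tree_layout`: list with `tree` (the displayed tree), `nodes`
#'   (data frame: `label`, `x`, `y`, `is_slot`, `collapsed`, `clone_size`)
#'   and `mode`.
#' @export
layout_tree <- function(tree, view = view_state(),
                        mode = c("cladogram", "branch_length")) {
  mode <- match.arg(mode)
  if (mode == "branch_length" && tree$bl_mode == "none") {
    warning("tree has no branch lengths; falling back to cladogram layout")
    mode <- "cladogram"
  }
  dt <- displayed_tree(tree, view)
  n <- length(dt$labels)
  collapsed <- intersect(view$collapsed, dt$labels)
  is_collapsed_root <- dt$labels %in% collapsed
  # a node is hidden if a strict ancestor is collapsed
  hidden <- logical(n)
  for (i in bfs_order(dt)) {
    p <- dt$parent[i]
    if (!is.na(p)) hidden[i] <- hidden[p] || is_collapsed_root[p]
  }
  visible <- !hidden
  # slots: visible leaves and visible collapsed roots, in preorder
  is_leaf <- lengths(dt$children) == 0L
  is_slot <- visible & (is_leaf | is_collapsed_root)
  pre <- dfs_order(dt)
  slots <- pre[is_slot[pre]]
  y <- rep(NA_real_, n)
  y[slots] <- seq_along(slots) - 1
  for (i in rev(pre)) {
    if (visible[i] && is.na(y[i])) {
      kids <- dt$children[[i]]
      kids <- kids[visible[kids] & !is.na(y[kids])]
      y[i] <- mean(y[kids])
    }
  }
  depth <- node_depths(dt)
  if (mode == "branch_length") {
    x <- unname(node_times(dt))
  } else {
    x <- as.numeric(depth)
    x[is_leaf & visible] <- max(depth[visible])
  }
  sizes <- vapply(dt$labels, function(l) length(clone_cells(dt, l)),
                  integer(1), USE.NAMES = FALSE)
  nodes <- data.frame(label = dt$labels[visible], x = x[visible],
                      y = y[visible], is_slot = is_slot[visible],
                      collapsed = is_collapsed_root[visible],
                      clone_size = sizes[visible],
                      stringsAsFactors = FALSE)
  structure(list(tree = dt, nodes = nodes, mode = mode),
            class = "tree_layout")
}

# --- Orthographic projection of the 3D panel ---------------------------

project_cells <- function(cells, azimuth, elevation) {
  a <- azimuth * pi / 180
  e <- elevation * pi / 180
  u <- cells$x * cos(a) + cells$y * sin(a)
  w <- -cells$x * sin(a) + cells$y * cos(a)
  v <- cells$z * cos(e) - w * sin(e)
  data.frame(cell = cells$cell, u = u, v = v, stringsAsFactors = FALSE)
}

# --- SVG assembly ------------------------------------------------------

fmt_svg <- function(x) sprintf("%.3f", x)

svg_rescale <- function(val, from, to) {
  span <- diff(from)
  if (span == 0) rep(mean(to), length(val))
  else to[1L] + (val - from[1L]) / span * diff(to)
}

#' Build the SVG document for a scene
#'
#' A pure function of the scene: two panels (lineage tree left, projected
#' 3D cells right) sharing the scene's per-cell colour map, with `data-cell`
#' attributes linking the two.  Byte-identical output for identical scenes.
#'
#' @param scn a [scene()].
#' @return SVG 1.1 document as a single string.
#' @export
build_svg <- function(scn) {
  stopifnot(inherits(scn, "scene"))
  W <- 960; H <- 480
  tree <- scn$joined$tree
  lay <- withCallingHandlers(
    layout_tree(tree, scn$view, scn$layout_mode),
    warning = function(w) invokeRestart("muffleWarning"))
  nd <- lay$nodes
  xr <- range(nd$x); yr <- range(nd$y)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  px <- svg_rescale(nd$x, xr, c(50, 430))
  py <- svg_rescale(nd$y, yr, c(40, 440))
  pos <- stats::setNames(seq_len(nrow(nd)), nd$label)
  cmap <- scn$colour_map
  cell_col <- function(lab) {
    if (lab %in% names(cmap)) cmap[[lab]] else "#555555"
  }
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
    W, H, W, H),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF" />', W, H),
    '<g id="tree-panel">')
  # elbow edges parent -> child
  dtree <- lay$tree
  for (k in seq_len(nrow(nd))) {
    lab <- nd$label[k]
    p <- dtree$parent[node_index(dtree, lab)]
    if (is.na(p)) next
    plab <- dtree$labels[p]
    if (!(plab %in% names(pos))) next
    kp <- pos[[plab]]
    out <- c(out, sprintf(
      '<path d="M %s %s V %s H %s" fill="none" stroke="#888888" stroke-width="1" />',
      fmt_svg(px[kp]), fmt_svg(py[kp]), fmt_svg(py[k]), fmt_svg(px[k])))
  }
  # nodes: slots are coloured cells/collapsed markers, internals are small
  for (k in seq_len(nrow(nd))) {
    lab <- nd$label[k]
    if (nd$collapsed[k]) {
      out <- c(out, sprintf(
        '<rect class="tree-node collapsed" data-cell="%s" x="%s" y="%s" width="8" height="8" fill="#555555" />',
        xml_escape(lab), fmt_svg(px[k] - 4), fmt_svg(py[k] - 4)),
        sprintf('<text x="%s" y="%s" font-size="9" font-family="sans-serif" fill="#333333">%d</text>',
                fmt_svg(px[k] + 6), fmt_svg(py[k] + 3), nd$clone_size[k]))
    } else if (nd$is_slot[k]) {
      out <- c(out, sprintf(
        '<circle class="tree-node cell" data-cell="%s" cx="%s" cy="%s" r="3.5" fill="%s" stroke="#333333" stroke-width="0.5" />',
        xml_escape(lab), fmt_svg(px[k]), fmt_svg(py[k]), cell_col(lab)))
    } else {
      out <- c(out, sprintf(
        '<circle class="tree-node internal" data-cell="%s" cx="%s" cy="%s" r="2" fill="#555555" />',
        xml_escape(lab), fmt_svg(px[k]), fmt_svg(py[k])))
    }
  }
  out <- c(out, "</g>", '<g id="cells-panel">')
  cells <- scn$joined$cells
  matched <- cells[cells$cell %in% scn$joined$matched, , drop = FALSE]
  proj <- project_cells(matched, scn$azimuth, scn$elevation)
  ur <- range(proj$u); vr <- range(proj$v)
  if (diff(ur) == 0) ur <- ur + c(-0.5, 0.5)
  if (diff(vr) == 0) vr <- vr + c(-0.5, 0.5)
  # uniform scale preserving aspect ratio
  s <- min(420 / diff(ur), 400 / diff(vr))
  cu <- 490 + (proj$u - ur[1L]) * s + (420 - diff(ur) * s) / 2
  cv <- 40 + (vr[2L] - proj$v) * s + (400 - diff(vr) * s) / 2
  ord <- order(proj$cell, method = "radix")
  for (k in ord) {
    out <- c(out, sprintf(
      '<circle class="cell3d" data-cell="%s" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.85" stroke="#333333" stroke-width="0.5" />',
      xml_escape(proj$cell[k]), fmt_svg(cu[k]), fmt_svg(cv[k]),
      fmt_svg(scn$sphere_radius), cell_col(proj$cell[k])))
  }
  out <- c(out, "</g>")
  if (!is.null(scn$legend)) {
    stops <- seq_colormap(seq(0, 1, length.out = 8L))
    xs <- seq(490, 790, length.out = 9L)
    for (k in seq_len(8L)) {
      out <- c(out, sprintf(
        '<rect x="%s" y="460" width="%s" height="10" fill="%s" />',
        fmt_svg(xs[k]), fmt_svg(xs[k + 1L] - xs[k]), stops[k]))
    }
    out <- c(out, sprintf(
      '<text x="490" y="456" font-size="10" font-family="sans-serif">%s: %s .. %s</text>',
      xml_escape(scn$legend$gene), fmt_svg(scn$legend$min),
      fmt_svg(scn$legend$max)))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Render a scene to a static image file
#'
#' SVG output is written directly from [build_svg()] and is byte-identical
#' across runs for the same scene; PNG output rasterizes the same geometry
#' through the `grDevices` png device.
#'
#' @param scn a [scene()].
#' @param path output file path.
#' @param format `"svg"` or `"png"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
render_static <- function(scn, path, format = c("auto", "svg", "png")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("svg", "png")) {
      stop("cannot infer format from extension '", format,
           "'; pass format = 'svg' or 'png'")
    }
  }
  if (format == "svg") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(build_svg(scn)), con)
    return(invisible(path))
  }
  grDevices::png(path, width = 960, height = 480)
  on.exit(grDevices::dev.off())
  plot_scene_base(scn)
  invisible(path)
}

# Base-graphics mirror of build_svg used for the PNG raster.
plot_scene_base <- function(scn) {
  graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  lay <- withCallingHandlers(
    layout_tree(scn$joined$tree, scn$view, scn$layout_mode),
    warning = function(w) invokeRestart("muffleWarning"))
  nd <- lay$nodes
  cmap <- scn$colour_map
  col_of <- function(lab) if (lab %in% names(cmap)) cmap[[lab]] else "#555555"
  graphics::plot(nd$x, -nd$y, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = "lineage")
  dtree <- lay$tree
  pos <- stats::setNames(seq_len(nrow(nd)), nd$label)
  for (k in seq_len(nrow(nd))) {
    p <- dtree$parent[node_index(dtree, nd$label[k])]
    if (is.na(p)) next
    plab <- dtree$labels[p]
    if (!(plab %in% names(pos))) next
    kp <- pos[[plab]]
    graphics::segments(nd$x[kp], -nd$y[kp], nd$x[kp], -nd$y[k])
    graphics::segments(nd$x[kp], -nd$y[k], nd$x[k], -nd$y[k])
  }
  cols <- vapply(nd$label, col_of, character(1))
  graphics::points(nd$x, -nd$y, pch = 19, cex = ifelse(nd$is_slot, 0.9, 0.4),
                   col = cols)
  cells <- scn$joined$cells
  matched <- cells[cells$cell %in% scn$joined$matched, , drop = FALSE]
  proj <- project_cells(matched, scn$azimuth, scn$elevation)
  graphics::plot(proj$u, proj$v, pch = 19, cex = scn$sphere_radius / 4,
                 col = vapply(proj$cell, col_of, character(1)),
                 axes = FALSE, xlab = "", ylab = "", main = "3D cells", asp = 1)
}

#' Render a scene to a standalone interactive HTML file
#'
#' A single self-contained HTML page embedding the scene's SVG plus a
#' small script: hovering a cell shows its ID and descendant counts (total
#' and on the 3D viewer), and clicking a tree node highlights its whole
#' clone in both panels.  No external resources are referenced.
#'
#' @param scn a [scene()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_html <- function(scn, path) {
  tree <- scn$joined$tree
  labs <- tree$labels
  info <- lapply(labs, function(l) {
    s <- descendant_summary(tree, l, scn$joined)
    list(total = s$total_descendants, viewer = s$on_viewer_descendants,
         clone = clone_cells(tree, l))
  })
  names(info) <- labs
  payload <- as.character(jsonlite::toJSON(info, auto_unbox = TRUE))
  svg <- build_svg(scn)
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\" />\n",
    "<title>lineage scene</title>\n",
    "<style>#tip{position:absolute;background:#fff;border:1px solid #999;",
    "padding:2px 6px;font:12px sans-serif;pointer-events:none;display:none}",
    ".hl{stroke:#000 !important;stroke-width:2 !important}</style>\n",
    "</head>\n<body>\n<div id=\"tip\"></div>\n", svg, "\n<script>\n",
    "var INFO = ", payload, ";\n",
    "var tip = document.getElementById('tip');\n",
    "function cellsOf(label){var i=INFO[label];return i?i.clone:[label];}\n",
    "document.querySelectorAll('[data-cell]').forEach(function(el){\n",
    "  el.addEventListener('mousemove', function(ev){\n",
    "    var l = el.getAttribute('data-cell'); var i = INFO[l] || {total:1,viewer:0};\n",
    "    tip.textContent = l + ' | descendants: ' + i.total + ' | on 3D viewer: ' + i.viewer;\n",
    "    tip.style.left = (ev.pageX + 12) + 'px'; tip.style.top = (ev.pageY + 12) + 'px';\n",
    "    tip.style.display = 'block';\n",
    "  });\n",
    "  el.addEventListener('mouseleave', function(){ tip.style.display='none'; });\n",
    "  el.addEventListener('click', function(){\n",
    "    var members = cellsOf(el.getAttribute('data-cell'));\n",
    "    var on = !el.classList.contains('hl');\n",
    "    document.querySelectorAll('.hl').forEach(function(e){e.classList.remove('hl');});\n",
    "    if (on) { el.classList.add('hl'); members.forEach(function(m){\n",
    "      document.querySelectorAll('[data-cell=\"'+m+'\"]').forEach(function(e){e.classList.add('hl');});\n",
    "    }); }\n",
    "  });\n",
    "});\n</script>\n</body>\n</html>\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(html), con)
  invisible(path)
}
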