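# CSV side-files carried alongside the lineage tree: 3D coordinates,
# categorical annotations, gene expression, and saved selections.  Dialect:
# comma-separated, mandatory header, case-insensitive header matching, UTF-8.

read_csv_text <- function(text) {
  con <- textConnection(text)
  on.exit(close(con))
  utils::read.csv(con, stringsAsFactors = FALSE, check.names = FALSE,
                  strip.white = TRUE)
}

#' Read a cell 3D-coordinate file
#'
#' The coordinate file is comma-separated with header `cell,X,Y,Z`
#' (matched case-insensitively after trimming) and one row per cell giving
#' its label and position in arbitrary but consistent spatial units.
#'
#' @param text CSV content as a single string, or a file path.
#' @return A `cell_table`: data frame with columns `cell`, `x`, `y`, `z`;
#'   labels unique, coordinates finite.
#' @export
read_coordinates <- function(text) {
  text <- slurp(text)
  df <- read_csv_text(text)
  hdr <- tolower(trimws(names(df)))
  want <- c("cell", "x", "y", "z")
  if (length(hdr) != 4L || !identical(hdr, want)) {
    stop("coordinate file must have header 'cell,X,Y,Z' (got: ",
         paste(names(df), collapse = ","), ")")
  }
  names(df) <- want
  if (nrow(df) == 0L) stop("coordinate file contains no cells")
  df$cell <- as.character(df$cell)
  if (anyDuplicated(df$cell)) {
    stop("duplicate cell labels in coordinates: ",
         paste(utils::head(unique(df$cell[duplicated(df$cell)]), 5L),
               collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) | any(!is.finite(v))) {
      bad <- df$cell[is.na(v) | !is.finite(v)]
      stop("non-numeric or non-finite ", toupper(col), " coordinate for cell(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    df[[col]] <- v
  }
  structure(df, class = c("cell_table", "data.frame"))
}

#' Write a cell table as a coordinate CSV
#' @param cells a `cell_table`.
#' @return CSV text with header `cell,X,Y,Z`.
#' @export
write_coordinates <- function(cells) {
  paste0("cell,X,Y,Z\n",
         paste0(csv_quote(cells$cell), ",", fmt_num(cells$x), ",",
                fmt_num(cells$y), ",", fmt_num(cells$z), collapse = "\n"),
         "\n")
}

#' Read a cell-annotation file
#'
#' Two columns, header `cell,annotation`: one categorical annotation (cell
#' type, fate, saved-selection name, ...) per cell.  Duplicate rows that
#' agree are collapsed; duplicates that conflict are an error.
#'
#' @param text CSV content as a single string, or a file path.
#' @return An `annotation_table`: data frame with columns `cell`,
#'   `annotation`.
#' @export
read_annotations <- function(text) {
  text <- slurp(text)
  df <- read_csv_text(text)
  hdr <- tolower(trimws(names(df)))
  if (length(hdr) != 2L || !identical(hdr, c("cell", "annotation"))) {
    stop("annotation file must have header 'cell,annotation' (got: ",
         paste(names(df), collapse = ","), ")")
  }
  names(df) <- c("cell", "annotation")
  df$cell <- as.character(df$cell)
  df$annotation <- as.character(df$annotation)
  if (anyDuplicated(df$cell)) {
    ag <- unique(df)
    if (anyDuplicated(ag$cell)) {
      bad <- unique(ag$cell[duplicated(ag$cell)])
      stop("conflicting annotations for cell(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    df <- ag
  }
  rownames(df) <- NULL
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Write saved selections as an annotation CSV
#'
#' Saved cell/clone selections are written in the annotation dialect
#' (`cell,annotation`, annotation = selection name) so the file can later
#' be reloaded as a cell-annotation file.
#'
#' @param selections named list of character vectors (selection name ->
#'   member cell labels), e.g. `view_state()$saved_selections`.
#' @return CSV text accepted by [read_annotations()].
#' @export
write_selection_csv <- function(selections) {
  stopifnot(is.list(selections), length(selections) > 0L,
            !is.null(names(selections)), all(nzchar(names(selections))))
  cell <- unlist(selections, use.names = FALSE)
  ann <- rep(names(selections), lengths(selections))
  if (anyDuplicated(cell)) {
    stop("a cell appears in more than one selection: ",
         paste(utils::head(unique(cell[duplicated(cell)]), 5L), collapse = ", "))
  }
  paste0("cell,annotation\n",
         paste0(csv_quote(cell), ",", csv_quote(ann), collapse = "\n"), "\n")
}

#' Read a gene-expression file
#'
#' Orientation: cells as rows, genes as columns.  The first column is
#' `cell` (case-insensitive); every remaining column is one gene.  Values
#' are non-negative reals; missing values become 0 with a warning.
#'
#' @param text CSV content as a single string, or a file path.
#' @return An `expression_table`: list with `cells` (labels), `genes`
#'   (names) and `values` (cells x genes numeric matrix).
#' @export
read_expression <- function(text) {
  text <- slurp(text)
  df <- read_csv_text(text)
  if (ncol(df) < 2L) stop("expression file has no gene columns")
  if (tolower(trimws(names(df)[1L])) != "cell") {
    stop("expression file must have 'cell' as its first column (got: ",
         names(df)[1L], ")")
  }
  genes <- trimws(names(df)[-1L])
  if (anyDuplicated(genes)) {
    stop("duplicate gene columns: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5L), collapse = ", "))
  }
  cells <- as.character(df[[1L]])
  if (anyDuplicated(cells)) {
    stop("duplicate cell rows in expression file: ",
         paste(utils::head(unique(cells[duplicated(cells)]), 5L), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  mode(vals) <- "numeric"
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " missing expression value(s) set to 0")
    vals[is.na(vals)] <- 0
  }
  if (any(vals < 0)) stop("negative expression values are not allowed")
  dimnames(vals) <- list(cells, genes)
  structure(list(cells = cells, genes = genes, values = vals),
            class = "expression_table")
}

#' Write an expression table as CSV
#' @param expr an `expression_table`.
#' @return CSV text readable by [read_expression()].
#' @export
write_expression <- function(expr) {
  rows <- vapply(seq_along(expr$cells), function(i) {
    paste0(csv_quote(expr$cells[i]), ",",
           paste(fmt_num(expr$values[i, ]), collapse = ","))
  }, character(1))
  paste0("cell,", paste(csv_quote(expr$genes), collapse = ","), "\n",
         paste(rows, collapse = "\n"), "\n")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table>", length(x$cells), "cells x", length(x$genes),
      "genes\n")
  invisible(x)
}

#' Autofill lookup of gene names by prefix
#'
#' Case-insensitive prefix search over the gene names of an expression
#' table, label-sorted, with an exact (case-insensitive) match first.
#'
#' @param expr an `expression_table`.
#' @param prefix search prefix; `""` matches all genes.
#' @return Character vector of matching gene names (possibly empty).
#' @export
gene_lookup <- function(expr, prefix = "") {
  stopifnot(is.character(prefix), length(prefix) == 1L)
  hit <- startsWith(tolower(expr$genes), tolower(prefix))
  out <- sort(expr$genes[hit], method = "radix")
  exact <- tolower(out) == tolower(prefix)
  c(out[exact], out[!exact])
}

#' Join a lineage tree with a cell-coordinate table
#'
#' The lineage view and the 3D view are linked by cell label: the join
#' records which cells appear in both (matched), only in the tree
#' (tree_only — legal partial coverage, e.g. positions mapped for a subset
#' of the lineage), or only in the coordinates (coords_only).  An empty
#' intersection is an error; non-empty differences raise a warning with
#' counts.
#'
#' @param tree a `lineage_tree`.
#' @param cells a `cell_table`.
#' @return A `joined_dataset`: list with `tree`, `cells`, `matched`,
#'   `tree_only`, `coords_only` (character vectors of labels).
#' @export
join_cells <- function(tree, cells) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(cells, "cell_table"))
  leaves <- leaf_labels(tree)
  matched <- intersect(leaves, cells$cell)
  tree_only <- setdiff(leaves, cells$cell)
  coords_only <- setdiff(cells$cell, leaves)
  if (!length(matched)) {
    stop("no cell labels shared between tree and coordinates; tree has e.g. ",
         paste(utils::head(leaves, 5L), collapse = ", "),
         " and coordinates have e.g. ",
         paste(utils::head(cells$cell, 5L), collapse = ", "))
  }
  if (length(tree_only) || length(coords_only)) {
    warning("partial join: ", length(matched), " matched, ",
            length(tree_only), " cells only in tree, ",
            length(coords_only), " only in coordinates")
  }
  structure(list(tree = tree, cells = cells, matched = matched,
                 tree_only = tree_only, coords_only = coords_only),
            class = "joined_dataset")
}

#' @export
print.joined_dataset <- function(x, ...) {
  cat("<joined_dataset>", length(x$matched), "matched cells;",
      length(x$tree_only), "tree-only;", length(x$coords_only),
      "coordinates-only\n")
  invisible(x)
}

# --- MaMuT / TrackMate-style tracking XML ------------------------------

#' Import a MaMuT single-XML tracking file
#'
#' Reads the TrackMate-family schema (`Model/AllSpots/SpotsInFrame/Spot`
#' with id, frame and 3D position; `Model/AllTracks/Track/Edge` linking a
#' source spot to a target spot) and reconstructs the cell lineage: chains
#' of single-successor spots collapse into one tree edge whose length is
#' the frame span, spots with two or more successors become division
#' nodes, and spots with no successor become leaf cells.  Cells are
#' labelled by the spot `name` attribute when present, falling back to the
#' numeric spot id.  The returned coordinates are each leaf's final-frame
#' position.
#'
#' @param text XML content as a single string, or a file path.
#' @return List with `tree` (a `lineage_tree`, `bl_mode = "relative"`,
#'   lengths in frames) and `cells` (a `cell_table` at the final frame of
#'   each track).
#' @export
import_mamut <- function(text) {
  text <- slurp(text)
  doc <- xml2::read_xml(text)
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots/SpotsInFrame/Spot")
  if (!length(spots)) stop("no spots found under Model/AllSpots")
  spot_id <- xml2::xml_attr(spots, "ID")
  spot_name <- xml2::xml_attr(spots, "name")
  frame <- as.integer(xml2::xml_attr(spots, "FRAME"))
  px <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  py <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  pz <- as.numeric(xml2::xml_attr(spots, "POSITION_Z"))
  if (anyNA(frame) || anyNA(px) || anyNA(py) || anyNA(pz)) {
    stop("spot with missing FRAME or POSITION_X/Y/Z attribute")
  }
  if (anyDuplicated(spot_id)) stop("duplicate spot IDs")
  idx <- stats::setNames(seq_along(spot_id), spot_id)

  edges <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track/Edge")
  src <- xml2::xml_attr(edges, "SPOT_SOURCE_ID")
  tgt <- xml2::xml_attr(edges, "SPOT_TARGET_ID")
  bad <- !(src %in% spot_id) | !(tgt %in% spot_id)
  if (any(bad)) {
    stop("dangling edge reference(s): ",
         paste(utils::head(unique(c(src[bad], tgt[bad])), 5L), collapse = ", "))
  }
  succ <- rep(list(integer()), length(spot_id))
  has_parent <- logical(length(spot_id))
  for (k in seq_along(src)) {
    s <- idx[[src[k]]]
    t <- idx[[tgt[k]]]
    succ[[s]] <- c(succ[[s]], t)
    if (has_parent[t]) stop("spot ", spot_id[t], " has multiple incoming edges")
    has_parent[t] <- TRUE
  }
  roots <- which(!has_parent)
  if (length(roots) != 1L) {
    stop("expected a single lineage (one root spot), found ", length(roots),
         " roots: ", paste(utils::head(spot_id[roots], 5L), collapse = ", "))
  }

  # collapse single-successor chains root-downward into tree edges
  labels <- character(0)
  parent <- integer(0)
  blen <- numeric(0)
  node_frame <- integer(0)
  leaf_spot <- integer(0)
  node_label <- function(s) {
    nm <- spot_name[s]
    if (!is.na(nm) && nzchar(nm)) nm else spot_id[s]
  }
  # queue of (start spot of a branch, tree index of its parent node)
  queue_spot <- roots
  queue_parent <- NA_integer_
  guard <- 0L
  while (length(queue_spot)) {
    s <- queue_spot[[1L]]
    p <- queue_parent[[1L]]
    queue_spot <- queue_spot[-1L]
    queue_parent <- queue_parent[-1L]
    while (length(succ[[s]]) == 1L) {
      s <- succ[[s]]
      guard <- guard + 1L
      if (guard > length(spot_id)) stop("cyclic spot links detected")
    }
    i <- length(labels) + 1L
    labels[i] <- node_label(s)
    parent[i] <- p
    node_frame[i] <- frame[s]
    # branch length = frame span between this node's spot and its parent
    # node's spot; the root's own length anchors time zero at frame zero
    blen[i] <- if (is.na(p)) frame[s] else frame[s] - node_frame[p]
    if (!length(succ[[s]])) leaf_spot[i] <- s else leaf_spot[i] <- NA_integer_
    kids <- succ[[s]]
    if (length(kids)) {
      queue_spot <- c(queue_spot, kids)
      queue_parent <- c(queue_parent, rep(i, length(kids)))
    }
  }
  if (anyDuplicated(labels)) {
    stop("duplicate cell labels derived from spots: ",
         paste(utils::head(unique(labels[duplicated(labels)]), 5L),
               collapse = ", "))
  }
  tree <- lineage_tree(labels, parent, blen, "relative")
  leaf_i <- which(!is.na(leaf_spot))
  cells <- data.frame(cell = labels[leaf_i],
                      x = px[leaf_spot[leaf_i]],
                      y = py[leaf_spot[leaf_i]],
                      z = pz[leaf_spot[leaf_i]],
                      stringsAsFactors = FALSE)
  cells <- structure(cells, class = c("cell_table", "data.frame"))
  list(tree = tree, cells = cells)
}

# Accept either literal content or a path to a file with that content.
slurp <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[\n,;<(]", text) && file.exists(text)) {
    return(paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n"))
  }
  text
}
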