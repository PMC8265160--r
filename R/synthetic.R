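# Synthetic lineage data: stochastic division trees, spatially coherent cell
# placements, clade annotations, marker-gene expression, and tracking-XML
# fixtures.  Everything is deterministic under a fixed seed so generated
# datasets can serve as ground truth for the analysis operations.

#' Configuration for synthetic lineage generation
#'
#' @param n_leaves target number of cells at the final time point (`>= 1`).
#' @param seed integer RNG seed; identical configurations give identical
#'   output.
#' @param division_waiting waiting-time law between divisions:
#'   `list(kind = "exponential", rate = <r>)` (default, rate 1 per time
#'   unit) or `list(kind = "fixed", value = <v>)` for synchronous analytic
#'   cases.
#' @param spatial_step displacement per division in spatial units
#'   (default 1).
#' @param coherence in `[0, 1]`: how strongly daughter cells inherit their
#'   mother's direction of motion; high values make clones spatially
#'   compact and mutually separated (default 0.9).
#' @param n_genes number of genes in generated expression tables
#'   (default 5).
#' @param n_marker_clades number of depth-2 clades given a fate label and
#'   a marker gene (default 2).
#' @param polytomy_rate probability in `[0, 1)` that a division produces
#'   three daughters instead of two, leaving the lineage incompletely
#'   resolved (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves = 64L, seed = 1L,
                       division_waiting = list(kind = "exponential", rate = 1),
                       spatial_step = 1, coherence = 0.9,
                       n_genes = 5L, n_marker_clades = 2L,
                       polytomy_rate = 0) {
  stopifnot(n_leaves >= 1L, spatial_step >= 0,
            coherence >= 0, coherence <= 1,
            n_genes >= 0L, n_marker_clades >= 0L,
            polytomy_rate >= 0, polytomy_rate < 1,
            is.list(division_waiting),
            division_waiting$kind %in% c("exponential", "fixed"))
  structure(list(n_leaves = as.integer(n_leaves), seed = as.integer(seed),
                 division_waiting = division_waiting,
                 spatial_step = spatial_step, coherence = coherence,
                 n_genes = as.integer(n_genes),
                 n_marker_clades = as.integer(n_marker_clades),
                 polytomy_rate = polytomy_rate),
            class = "sim_config")
}

draw_waiting <- function(cfg, n = 1L) {
  dw <- cfg$division_waiting
  if (dw$kind == "fixed") rep(dw$value, n) else stats::rexp(n, rate = dw$rate)
}

#' Simulate a stochastic cell-lineage tree
#'
#' A branching process: the founder cell divides at time 0 and every
#' daughter schedules its own division after a waiting time drawn from the
#' configured law, until at least `n_leaves` lineages are alive; all
#' surviving lineages then persist to a common final time point.  With
#' `polytomy_rate > 0` a division occasionally yields three daughters
#' (an unresolved division).  Cells are labelled `c1`, `c2`, ... in birth
#' order; branch lengths are relative (division intervals).
#'
#' The attached division log is independent ground truth for time cuts:
#' the number of lineages alive at time `t` is one plus the extra lineages
#' created by divisions strictly before `t`.
#'
#' @param cfg a [sim_config()].
#' @return A `lineage_tree` (`bl_mode = "relative"`) with attributes
#'   `division_log` (data frame: `time`, `parent`, `n_daughters`) and
#'   `final_time`.
#' @export
simulate_lineage <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  labels <- "c1"
  parent <- NA_integer_
  birth <- 0           # time each cell came into existence
  div_time <- NA_real_ # division time of internal nodes
  counter <- 1L

  if (cfg$n_leaves == 1L) {
    tr <- lineage_tree("c1", NA_integer_, 0, "relative")
    attr(tr, "division_log") <- data.frame(time = numeric(0),
                                           parent = character(0),
                                           n_daughters = integer(0))
    attr(tr, "final_time") <- 0
    return(tr)
  }

  # alive lineages: node index and scheduled division time
  alive <- 1L
  sched <- 0  # the founder divides at time 0
  log_time <- numeric(0)
  log_parent <- character(0)
  log_daughters <- integer(0)

  while (length(alive) < cfg$n_leaves) {
    j <- which.min(sched)
    node <- alive[j]
    t_div <- sched[j]
    alive <- alive[-j]
    sched <- sched[-j]
    n_d <- if (stats::runif(1) < cfg$polytomy_rate) 3L else 2L
    div_time[node] <- t_div
    log_time <- c(log_time, t_div)
    log_parent <- c(log_parent, labels[node])
    log_daughters <- c(log_daughters, n_d)
    for (d in seq_len(n_d)) {
      counter <- counter + 1L
      i <- length(labels) + 1L
      labels[i] <- paste0("c", counter)
      parent[i] <- node
      birth[i] <- t_div
      div_time[i] <- NA_real_
      alive <- c(alive, i)
      sched <- c(sched, t_div + draw_waiting(cfg))
    }
  }

  final_time <- max(log_time) + mean_waiting(cfg)
  # relative branch length: division (or final) time minus parent's division
  bl <- vapply(seq_along(labels), function(i) {
    end <- if (i %in% alive) final_time else div_time[i]
    end - birth[i]
  }, numeric(1))
  bl[1L] <- 0  # the founder divides at time zero

  tr <- lineage_tree(labels, parent, bl, "relative")
  attr(tr, "division_log") <- data.frame(time = log_time, parent = log_parent,
                                         n_daughters = log_daughters,
                                         stringsAsFactors = FALSE)
  attr(tr, "final_time") <- final_time
  tr
}

mean_waiting <- function(cfg) {
  dw <- cfg$division_waiting
  if (dw$kind == "fixed") dw$value else 1 / dw$rate
}

#' Lineages alive at a time point, from the division log
#'
#' Ground truth companion to [clones_at_time()]: counts lineages directly
#' from the simulation's division log, without touching the tree.
#'
#' @param log the `division_log` attribute of [simulate_lineage()] output.
#' @param t time point.
#' @return Integer count of lineages alive at `t` (1 before any division).
#' @export
alive_lineages <- function(log, t) {
  1L + sum((log$n_daughters[log$time < t] - 1L))
}

#' Place cells in space by a branching random walk
#'
#' Each daughter cell inherits its mother's position plus one displacement
#' step.  The step direction blends a heritable per-branch drift (weight
#' `coherence`) with fresh isotropic noise, so sibling subtrees drift
#' apart while cells within a clone stay together: with high coherence the
#' mean intra-clone pairwise distance falls below the inter-clone distance.
#'
#' @param tree a `lineage_tree` from [simulate_lineage()].
#' @param cfg the same [sim_config()].
#' @return A `cell_table` with one row per leaf cell.
#' @export
place_cells <- function(tree, cfg) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)  # decouple placement noise from topology noise
  n <- length(tree$labels)
  pos <- matrix(0, n, 3L)
  drift <- matrix(0, n, 3L)
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) c(1, 0, 0) else v / nv
  }
  for (i in bfs_order(tree)) {
    p <- tree$parent[i]
    if (is.na(p)) {
      drift[i, ] <- unit(stats::rnorm(3))
      next
    }
    kick <- unit(stats::rnorm(3))
    drift[i, ] <- unit(cfg$coherence * drift[p, ] + (1 - cfg$coherence) * kick)
    step <- cfg$coherence * drift[i, ] + (1 - cfg$coherence) * stats::rnorm(3)
    pos[i, ] <- pos[p, ] + cfg$spatial_step * step
  }
  leaves <- which(lengths(tree$children) == 0L)
  structure(data.frame(cell = tree$labels[leaves],
                       x = pos[leaves, 1L], y = pos[leaves, 2L],
                       z = pos[leaves, 3L], stringsAsFactors = FALSE),
            class = c("cell_table", "data.frame"))
}

depth2_founders <- function(tree) {
  depth <- node_depths(tree)
  is_leaf <- lengths(tree$children) == 0L
  tree$labels[(depth == 2L) | (is_leaf & depth < 2L)]
}

#' Annotate synthetic fate clades
#'
#' Picks `n_marker_clades` of the depth-2 clones (seeded sample) and labels
#' their member cells `fate_1`, `fate_2`, ...; all remaining cells are
#' labelled `other`.  The chosen founder-to-fate mapping is attached as
#' ground truth.
#'
#' @param tree a `lineage_tree`.
#' @param cfg a [sim_config()].
#' @return An `annotation_table` with attribute `clades` (named character
#'   vector fate -> founder label).
#' @export
annotate_clades <- function(tree, cfg) {
  founders <- depth2_founders(tree)
  if (cfg$n_marker_clades > length(founders)) {
    stop("n_marker_clades (", cfg$n_marker_clades,
         ") exceeds the number of depth-2 clones (", length(founders), ")")
  }
  set.seed(cfg$seed + 2L)
  chosen <- sort(sample(founders, cfg$n_marker_clades))
  leaves <- leaf_labels(tree)
  ann <- rep("other", length(leaves))
  names(ann) <- leaves
  fates <- character(0)
  for (k in seq_along(chosen)) {
    fate <- paste0("fate_", k)
    ann[clone_cells(tree, chosen[k])] <- fate
    fates[fate] <- chosen[k]
  }
  out <- structure(data.frame(cell = leaves, annotation = unname(ann),
                              stringsAsFactors = FALSE),
                   class = c("annotation_table", "data.frame"))
  attr(out, "clades") <- fates
  out
}

#' Generate marker-gene expression for synthetic clades
#'
#' One marker gene per annotated clade, expressed high (log-normal around
#' 10) inside the clade and low (around 0.1) outside, plus unstructured
#' background genes up to `n_genes`.  The marker-to-founder mapping is
#' attached as ground truth.
#'
#' @param tree a `lineage_tree`.
#' @param cfg a [sim_config()]; requires
#'   `n_genes >= n_marker_clades`.
#' @return An `expression_table` with attribute `markers` (named character
#'   vector gene -> founder label).
#' @export
express_markers <- function(tree, cfg) {
  if (cfg$n_genes < cfg$n_marker_clades) {
    stop("n_genes must be at least n_marker_clades")
  }
  ann <- annotate_clades(tree, cfg)  # same seeded clade choice
  clades <- attr(ann, "clades")
  leaves <- leaf_labels(tree)
  set.seed(cfg$seed + 3L)
  n_bg <- cfg$n_genes - cfg$n_marker_clades
  genes <- c(if (length(clades)) paste0("marker_", seq_along(clades)),
             if (n_bg > 0L) paste0("gene_", seq_len(n_bg)))
  vals <- matrix(0, length(leaves), length(genes),
                 dimnames = list(leaves, genes))
  markers <- character(0)
  for (k in seq_along(clades)) {
    inside <- leaves %in% clone_cells(tree, clades[[k]])
    mu <- ifelse(inside, log(10), log(0.1))
    vals[, k] <- stats::rlnorm(length(leaves), meanlog = mu, sdlog = 0.5)
    markers[genes[k]] <- clades[[k]]
  }
  if (n_bg > 0L) {
    for (k in seq_len(n_bg)) {
      vals[, length(clades) + k] <-
        stats::rlnorm(length(leaves), meanlog = 0, sdlog = 1)
    }
  }
  out <- structure(list(cells = leaves, genes = genes, values = vals),
                   class = "expression_table")
  attr(out, "markers") <- markers
  out
}

#' Write a MaMuT-style tracking XML for a lineage tree
#'
#' Emits the TrackMate-family skeleton ([import_mamut()]'s input): one spot
#' per frame along every branch, chained by edges, with division spots
#' linking to the first spots of the daughter branches.  Branch lengths
#' must be relative non-negative integers (frame spans).  Spot positions
#' follow a seeded random walk; each leaf's final spot carries the
#' coordinates returned alongside the XML.
#'
#' @param tree a `lineage_tree`, `bl_mode = "relative"`, integer lengths.
#' @param seed RNG seed for the positional walk.
#' @return List with `xml` (text) and `cells` (a `cell_table` of the
#'   final-frame leaf positions).
#' @export
write_mamut_xml <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (tree$bl_mode != "relative") {
    stop("write_mamut_xml requires relative branch lengths (frame spans)")
  }
  bl <- tree$branch_length
  if (any(bl != round(bl)) || any(bl < 0)) {
    stop("branch lengths must be non-negative integers (frames)")
  }
  set.seed(seed)
  times <- node_times(tree)  # node frame numbers
  n <- length(tree$labels)

  sid <- 0L
  spot_rows <- list()  # per frame: vectors of xml lines
  edge_lines <- character(0)
  new_spot <- function(frame, pos, name = NULL) {
    sid <<- sid + 1L
    nm <- if (is.null(name)) paste0("s", sid) else name
    spot_rows[[length(spot_rows) + 1L]] <<- list(
      frame = frame,
      line = sprintf(
        '<Spot ID="%d" name="%s" FRAME="%d" POSITION_X="%s" POSITION_Y="%s" POSITION_Z="%s" />',
        sid, xml_escape(nm), frame, fmt_num(pos[1]), fmt_num(pos[2]),
        fmt_num(pos[3])))
    sid
  }
  link <- function(a, b) {
    edge_lines[length(edge_lines) + 1L] <<-
      sprintf('<Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" />', a, b)
  }

  node_spot <- integer(n)   # the spot carrying each tree node's label
  node_pos <- matrix(0, n, 3L)
  for (i in bfs_order(tree)) {
    p <- tree$parent[i]
    if (is.na(p)) {
      node_pos[i, ] <- c(0, 0, 0)
      node_spot[i] <- new_spot(as.integer(times[i]), node_pos[i, ],
                               tree$labels[i])
      next
    }
    span <- as.integer(bl[i])
    prev <- node_spot[p]
    pos <- node_pos[p, ]
    f0 <- as.integer(times[p])
    if (span == 0L) {
      stop("zero-length branch at '", tree$labels[i],
           "': tracking XML needs at least one frame per branch")
    }
    for (f in seq_len(span)) {
      pos <- pos + stats::rnorm(3, sd = 0.5)
      last <- f == span
      s <- new_spot(f0 + f, pos, if (last) tree$labels[i] else NULL)
      link(prev, s)
      prev <- s
    }
    node_spot[i] <- prev
    node_pos[i, ] <- pos
  }

  frames <- vapply(spot_rows, function(r) r$frame, numeric(1))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<TrackMate version="1.0">', "<Model>", "<AllSpots>")
  for (f in sort(unique(frames))) {
    lines <- c(lines, sprintf('<SpotsInFrame frame="%d">', as.integer(f)),
               vapply(spot_rows[frames == f], function(r) r$line, character(1)),
               "</SpotsInFrame>")
  }
  lines <- c(lines, "</AllSpots>", "<AllTracks>", '<Track TRACK_ID="0">',
             edge_lines, "</Track>", "</AllTracks>", "</Model>",
             "</TrackMate>")

  leaves <- which(lengths(tree$children) == 0L)
  cells <- structure(data.frame(cell = tree$labels[leaves],
                                x = node_pos[leaves, 1L],
                                y = node_pos[leaves, 2L],
                                z = node_pos[leaves, 3L],
                                stringsAsFactors = FALSE),
                     class = c("cell_table", "data.frame"))
  list(xml = paste(lines, collapse = "\n"), cells = cells)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Generate the packaged suite of four example-shaped datasets
#'
#' Writes four small synthetic datasets that together cover the feature
#' combinations seen in published lineage resources: a nematode-larva-like
#' set (Newick, relative branch lengths, annotations, coordinates for only
#' a subset of the lineage), an ascidian-gastrula-like set (Newick, no
#' branch lengths, annotations and gene expression), a crustacean-limb-like
#' set (JSON and Newick, absolute branch lengths), and an organoid-like set
#' (JSON only).  Every dataset loads end-to-end through the package's
#' readers.
#'
#' @param dir output directory (created if needed); one subdirectory per
#'   dataset.
#' @param seed integer seed.
#' @param n_cells approximate cells per dataset (default 100).
#' @return Invisibly, a named list of the dataset directories with their
#'   loaded contents.
#' @export
fixture_suite <- function(dir, seed = 1L, n_cells = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  wf <- function(path, text) {
    if (!endsWith(text, "\n")) text <- paste0(text, "\n")
    writeLines(text, path, sep = "", useBytes = TRUE)
  }

  # 1. worm-like: newick + relative BL + annotations; partial 3D coverage
  d <- file.path(dir, "worm_like"); dir.create(d, showWarnings = FALSE)
  cfg <- sim_config(n_leaves = n_cells, seed = seed, n_marker_clades = 2L)
  tr <- simulate_lineage(cfg)
  cells <- place_cells(tr, cfg)
  set.seed(seed + 10L)
  keep <- sort(sample(nrow(cells), floor(nrow(cells) * 0.64)))
  partial <- structure(cells[keep, , drop = FALSE],
                       class = c("cell_table", "data.frame"))
  wf(file.path(d, "lineage.nwk"), to_newick(tr))
  wf(file.path(d, "coordinates.csv"), write_coordinates(partial))
  wf(file.path(d, "annotations.csv"),
     paste0("cell,annotation\n",
            paste0(annotate_clades(tr, cfg)$cell, ",",
                   annotate_clades(tr, cfg)$annotation, collapse = "\n"), "\n"))
  out$worm_like <- list(dir = d, tree = tr, cells = partial)

  # 2. gastrula-like: newick, no BL, annotations + expression
  d <- file.path(dir, "gastrula_like"); dir.create(d, showWarnings = FALSE)
  cfg <- sim_config(n_leaves = n_cells, seed = seed + 1L,
                    n_genes = 8L, n_marker_clades = 3L)
  tr <- simulate_lineage(cfg)
  cells <- place_cells(tr, cfg)
  trn <- lineage_tree(tr$labels, tr$parent, NULL, "none")
  wf(file.path(d, "lineage.nwk"), to_newick(trn))
  wf(file.path(d, "coordinates.csv"), write_coordinates(cells))
  ann <- annotate_clades(tr, cfg)
  wf(file.path(d, "annotations.csv"),
     paste0("cell,annotation\n",
            paste0(ann$cell, ",", ann$annotation, collapse = "\n"), "\n"))
  wf(file.path(d, "expression.csv"), write_expression(express_markers(tr, cfg)))
  out$gastrula_like <- list(dir = d, tree = trn, cells = cells)

  # 3. limb-like: json and newick, absolute BL
  d <- file.path(dir, "limb_like"); dir.create(d, showWarnings = FALSE)
  cfg <- sim_config(n_leaves = n_cells, seed = seed + 2L)
  tr <- convert_bl_mode(simulate_lineage(cfg), "absolute")
  cells <- place_cells(tr, cfg)
  wf(file.path(d, "lineage.json"), to_json(tr))
  wf(file.path(d, "lineage.nwk"), to_newick(tr))
  wf(file.path(d, "coordinates.csv"), write_coordinates(cells))
  out$limb_like <- list(dir = d, tree = tr, cells = cells)

  # 4. organoid-like: json only, no BL, no annotations
  d <- file.path(dir, "organoid_like"); dir.create(d, showWarnings = FALSE)
  cfg <- sim_config(n_leaves = n_cells, seed = seed + 3L, coherence = 0.95)
  tr <- simulate_lineage(cfg)
  cells <- place_cells(tr, cfg)
  trn <- lineage_tree(tr$labels, tr$parent, NULL, "none")
  wf(file.path(d, "lineage.json"), to_json(trn))
  wf(file.path(d, "coordinates.csv"), write_coordinates(cells))
  out$organoid_like <- list(dir = d, tree = trn, cells = cells)

  invisible(out)
}
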