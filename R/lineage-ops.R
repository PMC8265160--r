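#' Cell clone of an ancestor
#'
#' The clone of a cell is the complete set of its descendant cells: here,
#' the leaf labels of the subtree rooted at `ancestor`.  A leaf is its own
#' clone of size one.
#'
#' @param tree a `lineage_tree`.
#' @param ancestor node label.
#' @return Character vector of leaf labels (deterministic preorder).
#' @export
clone_cells <- function(tree, ancestor) {
  i <- node_index(tree, ancestor)
  idx <- dfs_order(tree, i)
  tree$labels[idx[lengths(tree$children[idx]) == 0L]]
}

#' Descendant counts for a node, total and on the 3D viewer
#'
#' The hover summary of the lineage view: a node's clone size, and how many
#' of those cells also have 3D coordinates (are "on the viewer").  A leaf
#' counts itself, so the totals equal clone sizes.
#'
#' @param tree a `lineage_tree`.
#' @param node node label.
#' @param joined a `joined_dataset` from [join_cells()], or `NULL` when no
#'   coordinates are loaded (then `on_viewer` is 0).
#' @return List with `label`, `total_descendants`, `on_viewer_descendants`.
#' @export
descendant_summary <- function(tree, node, joined = NULL) {
  members <- clone_cells(tree, node)
  on_viewer <- if (is.null(joined)) 0L else sum(members %in% joined$matched)
  list(label = node,
       total_descendants = length(members),
       on_viewer_descendants = as.integer(on_viewer))
}

new_clone_partition <- function(cut_kind, cut_value, groups) {
  structure(list(cut_kind = cut_kind, cut_value = cut_value, groups = groups),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat("<clone_partition> cut:", x$cut_kind,
      if (!is.null(x$cut_value)) paste0("(", x$cut_value, ")"), "-",
      length(x$groups), "groups,", sum(lengths(x$groups)), "cells\n")
  invisible(x)
}

#' Clones founded by a set of ancestors
#'
#' Colours several hand-picked clones at once: each ancestor founds the
#' group of its descendant cells.
#'
#' @param tree a `lineage_tree`.
#' @param ancestors character vector of node labels.
#' @return A `clone_partition` (`cut_kind = "ancestors"`); groups may overlap
#'   only if one ancestor is nested in another, which is rejected.
#' @export
clones_of_ancestors <- function(tree, ancestors) {
  groups <- lapply(ancestors, function(a) clone_cells(tree, a))
  names(groups) <- ancestors
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("ancestor set is nested: clones overlap at cell(s) ",
         paste(utils::head(unique(all_members[duplicated(all_members)]), 5L),
               collapse = ", "))
  }
  new_clone_partition("ancestors", NULL, groups)
}

#' Clone partition at a division depth
#'
#' Partitions the cells into the clones founded `k` divisions after the
#' root: founders are all nodes at edge-depth exactly `k`, plus every leaf
#' shallower than `k` (a cell that stopped dividing early persists as its
#' own clone).  `k = 0` returns the single root clone.
#'
#' @param tree a `lineage_tree`.
#' @param k number of divisions from the root (depth), `>= 0`.
#' @return A `clone_partition` whose groups are pairwise disjoint and cover
#'   every leaf.
#' @export
clones_at_division_depth <- function(tree, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != round(k)) {
    stop("division depth k must be a single integer >= 0")
  }
  depth <- node_depths(tree)
  is_leaf <- lengths(tree$children) == 0L
  founders <- tree$labels[(depth == k) | (is_leaf & depth < k)]
  groups <- lapply(founders, function(f) clone_cells(tree, f))
  names(groups) <- founders
  new_clone_partition("division_depth", as.integer(k), groups)
}

#' Clone partition at a developmental time
#'
#' For trees with branch lengths, partitions the cells alive at time `t`
#' into clones.  An edge from parent `p` to child `c` is alive at `t` iff
#' `time(p) < t <= time(c)`; each alive edge founds the clone of its child.
#' Leaves whose time is before `t` persist as singleton clones (the 3D view
#' shows cells at the final time point, so every cell belongs to some clone
#' at late `t`).  At `t <= time(root)` the root founds the single group of
#' all cells.
#'
#' @param tree a `lineage_tree` with `bl_mode` other than `"none"`.
#' @param t time point, `>= 0`, on the scale of [node_times()].
#' @return A `clone_partition`.
#' @export
clones_at_time <- function(tree, t) {
  if (tree$bl_mode == "none") {
    stop("clones_at_time requires branch lengths (bl_mode is 'none')")
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("time t must be a single number >= 0")
  }
  times <- node_times(tree)
  if (t <= times[[tree$root]]) {
    groups <- list(clone_cells(tree, tree$labels[tree$root]))
    names(groups) <- tree$labels[tree$root]
    return(new_clone_partition("time", t, groups))
  }
  is_leaf <- lengths(tree$children) == 0L
  founders <- character(0)
  for (i in seq_along(tree$labels)) {
    p <- tree$parent[i]
    alive_edge <- !is.na(p) && times[p] < t && t <= times[i]
    terminated_leaf <- is_leaf[i] && times[i] < t
    if (alive_edge || terminated_leaf) {
      founders <- c(founders, tree$labels[i])
    }
  }
  groups <- lapply(founders, function(f) clone_cells(tree, f))
  names(groups) <- founders
  new_clone_partition("time", t, groups)
}

#' Most recent common ancestor of two nodes
#'
#' A node is its own ancestor, so `mrca(tree, x, x) = x` and the MRCA of a
#' node with one of its descendants is the node itself.
#'
#' @param tree a `lineage_tree`.
#' @param a,b node labels.
#' @return The MRCA's label.
#' @export
mrca <- function(tree, a, b) {
  ia <- node_index(tree, a)
  ib <- node_index(tree, b)
  anc <- function(i) {
    path <- i
    while (!is.na(tree$parent[path[length(path)]])) {
      path <- c(path, tree$parent[path[length(path)]])
    }
    path
  }
  pa <- anc(ia)
  pb <- anc(ib)
  common <- intersect(pa, pb)
  # first common element along a's upward walk is the deepest shared ancestor
  tree$labels[pa[match(TRUE, pa %in% common)]]
}

#' Lineage-relationship levels relative to a focal cell
#'
#' Quantifies the "degree of lineage relationship" of every cell to one
#' focal cell as the depth of their most recent common ancestor: cells in
#' the focal cell's smallest clones score high, distant relatives score
#' low, and the focal cell itself scores its own depth.  Thresholding the
#' level at `L` recovers exactly the clone of the focal cell's depth-`L`
#' ancestor — the nested set of clones the cell belongs to.
#'
#' @param tree a `lineage_tree`.
#' @param focal label of a leaf cell.
#' @return A `relationship_map`: list with `focal` and `level`, a named
#'   integer vector over all leaves.
#' @export
relationship_levels <- function(tree, focal) {
  i <- node_index(tree, focal)
  if (length(tree$children[[i]]) != 0L) {
    stop("focal cell '", focal, "' is not a leaf")
  }
  depth <- node_depths(tree)
  # ancestors of focal, root first
  path <- i
  while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
  on_path <- logical(length(tree$labels))
  on_path[path] <- TRUE
  leaves <- which(lengths(tree$children) == 0L)
  level <- integer(length(leaves))
  for (j in seq_along(leaves)) {
    k <- leaves[j]
    while (!on_path[k]) k <- tree$parent[k]
    level[j] <- depth[k]
  }
  structure(list(focal = focal,
                 level = stats::setNames(level, tree$labels[leaves])),
            class = "relationship_map")
}

#' @export
print.relationship_map <- function(x, ...) {
  cat("<relationship_map> focal:", x$focal, "-", length(x$level),
      "cells, levels 0 ..", max(x$level), "\n")
  invisible(x)
}

#' Root-to-cell path
#'
#' The full lineage history of a cell: the ordered chain of ancestors from
#' the root down to the cell itself.
#'
#' @param tree a `lineage_tree`.
#' @param cell node label.
#' @return Character vector of labels, root first, `cell` last.
#' @export
lineage_path <- function(tree, cell) {
  i <- node_index(tree, cell)
  path <- i
  while (!is.na(tree$parent[path[1L]])) path <- c(tree$parent[path[1L]], path)
  tree$labels[path]
}

# --- View state: collapse / expand / prune -----------------------------

#' Create an empty view state
#'
#' A `view_state` is an overlay on a lineage tree recording which branches
#' are collapsed (drawn as one marker) or pruned (excluded from display),
#' plus named saved cell selections.  It never mutates the tree itself.
#'
#' @return A `view_state` with empty collapsed/pruned sets and no selections.
#' @export
view_state <- function() {
  structure(list(collapsed = character(0), pruned = character(0),
                 saved_selections = list()),
            class = "view_state")
}

#' Collapse, expand or prune a branch of the displayed tree
#'
#' `collapse_node()` marks an internal node so its subtree renders as a
#' single marker carrying the clone size; `expand_node()` undoes it;
#' `prune_node()` excludes the subtree from the displayed tree (and from
#' cuts computed on the displayed tree); `unprune_node()` restores it.
#' All four are idempotent and return a new `view_state`.  A node cannot be
#' both collapsed and pruned: each operation removes the node from the
#' other set.
#'
#' @param tree a `lineage_tree`.
#' @param view a `view_state`.
#' @param node node label.
#' @return The updated `view_state`.
#' @export
collapse_node <- function(tree, view, node) {
  i <- node_index(tree, node)
  if (length(tree$children[[i]]) == 0L) {
    stop("cannot collapse leaf '", node, "': only internal nodes collapse")
  }
  view$pruned <- setdiff(view$pruned, node)
  view$collapsed <- union(view$collapsed, node)
  view
}

#' @rdname collapse_node
#' @export
expand_node <- function(tree, view, node) {
  node_index(tree, node)
  view$collapsed <- setdiff(view$collapsed, node)
  view
}

#' @rdname collapse_node
#' @export
prune_node <- function(tree, view, node) {
  i <- node_index(tree, node)
  if (i == tree$root) stop("cannot prune the root")
  view$collapsed <- setdiff(view$collapsed, node)
  view$pruned <- union(view$pruned, node)
  view
}

#' @rdname collapse_node
#' @export
unprune_node <- function(tree, view, node) {
  node_index(tree, node)
  view$pruned <- setdiff(view$pruned, node)
  view
}

#' Save a named cell selection in a view state
#'
#' @param view a `view_state`.
#' @param name selection name (reused names overwrite).
#' @param members character vector of cell labels.
#' @return The updated `view_state`.
#' @export
save_selection <- function(view, name, members) {
  stopifnot(inherits(view, "view_state"), is.character(name), nzchar(name))
  view$saved_selections[[name]] <- unique(as.character(members))
  view
}

#' Displayed tree after pruning
#'
#' Materializes the tree a view actually shows: pruned subtrees are removed
#' entirely.  Collapsed subtrees remain in the tree (collapse is a layout
#' concern; see [layout_tree()]).
#'
#' @param tree a `lineage_tree`.
#' @param view a `view_state`.
#' @return A `lineage_tree`.
#' @export
displayed_tree <- function(tree, view) {
  if (!length(view$pruned)) return(tree)
  drop <- unique(unlist(lapply(view$pruned, function(p) {
    dfs_order(tree, node_index(tree, p))
  })))
  if (tree$root %in% drop) stop("pruning removed the root")
  keep <- setdiff(seq_along(tree$labels), drop)
  remap <- integer(length(tree$labels))
  remap[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, remap[parent])
  bl <- if (is.null(tree$branch_length)) NULL else tree$branch_length[keep]
  lineage_tree(tree$labels[keep], parent, bl, tree$bl_mode)
}

#' Export a clone as a lineage JSON file
#'
#' Serializes the subtree rooted at `node` (labels and branch lengths
#' preserved) in the hierarchical JSON schema, for further analysis outside
#' the viewer.
#'
#' @param tree a `lineage_tree`.
#' @param node node label.
#' @return JSON text parseable by [parse_json_tree()].
#' @export
export_clone <- function(tree, node) {
  to_json(subtree_at(tree, node_index(tree, node)))
}

#' Subset the branches of a large unresolved tree for display
#'
#' Very large trees are displayed with only a subset of branches to keep
#' the lineage view legible; the reduction is applied automatically when
#' the tree holds more than `max_cells` cells (default 500) and is only
#' applicable to trees that are not completely resolved (that contain
#' polytomies).  At each polytomy only the first children in label-sorted
#' order are retained — never fewer than two — dropping children from the
#' largest polytomies first until the displayed leaf count fits the cap (or
#' no polytomy can shrink further).  Deterministic for a given tree.
#'
#' @param tree a `lineage_tree`.
#' @param max_cells display cap on the number of cells, default 500.
#' @return List with `tree` (the display tree), and `report`: a list with
#'   `applied` flag, `reason` (`"ok"`, `"not needed"` or
#'   `"not applicable"`), `hidden_cells` count, and `hidden_per_polytomy`,
#'   a named integer vector of dropped child counts.
#' @export
subset_branches <- function(tree, max_cells = 500L) {
  stopifnot(is.numeric(max_cells), length(max_cells) == 1L, max_cells >= 1)
  nl <- n_leaves(tree)
  if (nl <= max_cells) {
    return(list(tree = tree, report = list(
      applied = FALSE, reason = "not needed", hidden_cells = 0L,
      hidden_per_polytomy = stats::setNames(integer(0), character(0)))))
  }
  if (!has_polytomies(tree)) {
    return(list(tree = tree, report = list(
      applied = FALSE, reason = "not applicable", hidden_cells = 0L,
      hidden_per_polytomy = stats::setNames(integer(0), character(0)))))
  }
  # retained children per node, label-sorted so that dropping the last one
  # is deterministic
  retained <- lapply(tree$children, function(kids) {
    kids[order(tree$labels[kids], method = "radix")]
  })
  leaf_counts <- function() {
    # leaves under each node given current retention
    cnt <- integer(length(tree$labels))
    for (i in rev(bfs_order(tree))) {
      kids <- retained[[i]]
      cnt[i] <- if (!length(tree$children[[i]])) 1L else sum(cnt[kids])
    }
    cnt
  }
  repeat {
    cnt <- leaf_counts()
    excess <- cnt[tree$root] - max_cells
    if (excess <= 0L) break
    # shrinkable polytomies: >= 3 retained children and still reachable
    reach <- dfs_reachable(tree, retained)
    cand <- which(lengths(retained) >= 3L & reach)
    if (!length(cand)) break
    sizes <- lengths(retained)[cand]
    pick <- cand[order(-sizes, tree$labels[cand], method = "radix")][1L]
    # drop label-sorted last children of this polytomy while it helps
    while (excess > 0L && length(retained[[pick]]) > 2L) {
      dropped <- retained[[pick]][length(retained[[pick]])]
      retained[[pick]] <- retained[[pick]][-length(retained[[pick]])]
      excess <- excess - cnt[dropped]
    }
  }
  reach <- dfs_reachable(tree, retained)
  keep <- which(reach)
  remap <- integer(length(tree$labels))
  remap[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent <- ifelse(is.na(parent), NA_integer_, remap[parent])
  bl <- if (is.null(tree$branch_length)) NULL else tree$branch_length[keep]
  # restore original child order in the display tree
  disp <- lineage_tree(tree$labels[keep], parent, bl, tree$bl_mode)
  hidden <- vapply(seq_along(tree$labels), function(i) {
    length(tree$children[[i]]) - length(retained[[i]])
  }, integer(1))
  hid_idx <- which(hidden > 0L)
  list(tree = disp, report = list(
    applied = TRUE, reason = "ok",
    hidden_cells = nl - n_leaves(disp),
    hidden_per_polytomy = stats::setNames(hidden[hid_idx], tree$labels[hid_idx])))
}

# Reachability from the root following only retained children.
dfs_reachable <- function(tree, retained) {
  reach <- logical(length(tree$labels))
  stack <- tree$root
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    reach[i] <- TRUE
    stack <- c(stack, retained[[i]])
  }
  reach
}

#' Write a clone partition or relationship map as annotation-style CSV
#'
#' Uses the same two-column dialect as the cell-annotation file
#' (`cell,annotation`), so cut results can be reloaded as annotations.
#'
#' @param x a `clone_partition` or `relationship_map`.
#' @return CSV text with header `cell,annotation`.
#' @export
partition_to_csv <- function(x) {
  if (inherits(x, "clone_partition")) {
    cell <- unlist(x$groups, use.names = FALSE)
    ann <- rep(names(x$groups), lengths(x$groups))
  } else if (inherits(x, "relationship_map")) {
    cell <- names(x$level)
    ann <- as.character(x$level)
  } else {
    stop("expected a clone_partition or relationship_map")
  }
  ord <- order(cell, method = "radix")
  paste0("cell,annotation\n",
         paste0(csv_quote(cell[ord]), ",", csv_quote(ann[ord]), collapse = "\n"),
         "\n")
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}
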