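#' Rooted cell-lineage trees
#'
#' A `lineage_tree` stores a rooted genealogy of named cells: every node is a
#' cell, internal nodes are cells that divided, leaves are the cells present
#' at the final time point.  Nodes are held in a flat indexed table (label,
#' parent index, ordered child indices) with optional branch lengths in one
#' of two conventions:
#'
#' * `"relative"` — each node's branch length is the parent-to-child distance
#'   (division-to-division interval);
#' * `"absolute"` — each node's branch length is its cumulative distance from
#'   the root, which must be non-decreasing towards the leaves;
#' * `"none"` — no timing information.
#'
#' Labels are unique across the whole tree (leaf and internal) because they
#' are the join key linking the lineage view to the 3D cell view.
#'
#' @param labels character vector of node labels, one per node.
#' @param parent integer vector; `parent[i]` is the index of node `i`'s
#'   parent, `NA` for the root.
#' @param branch_length numeric vector of branch lengths or `NULL`.
#' @param bl_mode one of `"none"`, `"relative"`, `"absolute"`.
#' @return An object of class `lineage_tree` with fields `labels`, `parent`,
#'   `children` (list of integer vectors, in input order), `branch_length`,
#'   `bl_mode` and `root` (integer index).
#' @examples
#' tr <- lineage_tree(c("r", "A", "B"), c(NA, 1L, 1L))
#' n_leaves(tr)
#' @export
lineage_tree <- function(labels, parent, branch_length = NULL,
                         bl_mode = c("none", "relative", "absolute")) {
  bl_mode <- match.arg(bl_mode)
  labels <- as.character(labels)
  parent <- as.integer(parent)
  n <- length(labels)
  if (n == 0L) stop("a lineage tree must have at least one node")
  if (length(parent) != n) stop("labels and parent must have equal length")
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("duplicate node labels: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) {
    stop("tree must have exactly one root, found ", length(root))
  }
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer()
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) {
      if (p < 1L || p > n) stop("parent index out of range for node ", labels[i])
      children[[p]] <- c(children[[p]], i)
    }
  }
  tr <- structure(
    list(labels = labels, parent = parent, children = children,
         branch_length = branch_length, bl_mode = bl_mode, root = root),
    class = "lineage_tree"
  )
  validate_lineage_tree(tr)
  tr
}

#' Validate the structural invariants of a lineage tree
#'
#' Checks single-rootedness, reachability (no cycles, no orphans), label
#' uniqueness, branch-length consistency with `bl_mode`, and in absolute
#' mode the root-to-leaf monotonicity of cumulative distances.
#'
#' @param tree a `lineage_tree`.
#' @return `tree`, invisibly; errors describe the first violated invariant.
#' @export
validate_lineage_tree <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  n <- length(tree$labels)
  seen <- logical(n)
  stack <- tree$root
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[i]) stop("cycle detected at node ", tree$labels[i])
    seen[i] <- TRUE
    stack <- c(stack, tree$children[[i]])
  }
  if (!all(seen)) {
    stop("nodes unreachable from root: ",
         paste(utils::head(tree$labels[!seen], 5L), collapse = ", "))
  }
  if (tree$bl_mode == "none") {
    if (!is.null(tree$branch_length)) {
      stop("bl_mode is 'none' but branch lengths are present")
    }
  } else {
    bl <- tree$branch_length
    if (is.null(bl) || length(bl) != n) {
      stop("bl_mode is '", tree$bl_mode, "' but branch lengths are missing")
    }
    if (any(!is.na(bl) & bl < 0)) stop("negative branch lengths are not allowed")
    if (tree$bl_mode == "absolute") {
      for (i in seq_len(n)) {
        p <- tree$parent[i]
        if (!is.na(p) && !is.na(bl[i]) && !is.na(bl[p]) && bl[i] < bl[p]) {
          stop("absolute branch lengths decrease from '", tree$labels[p],
               "' (", bl[p], ") to '", tree$labels[i], "' (", bl[i], ")")
        }
      }
    }
  }
  invisible(tree)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", length(x$labels), " nodes, ", n_leaves(x),
      " cells (leaves), branch lengths: ", x$bl_mode, "\n", sep = "")
  cat("  root: ", x$labels[x$root], "\n", sep = "")
  if (has_polytomies(x)) cat("  contains polytomies (not completely resolved)\n")
  invisible(x)
}

node_index <- function(tree, label) {
  i <- match(label, tree$labels)
  if (anyNA(i)) {
    stop("unknown node label(s): ",
         paste(utils::head(label[is.na(i)], 5L), collapse = ", "))
  }
  i
}

#' Leaf labels of a lineage tree
#'
#' Leaves (zero-children nodes) are the cells of the final time point.
#'
#' @param tree a `lineage_tree`.
#' @return Character vector of leaf labels in node-table order.
#' @export
leaf_labels <- function(tree) {
  tree$labels[lengths(tree$children) == 0L]
}

#' Number of cells (leaves) in a lineage tree
#' @param tree a `lineage_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) sum(lengths(tree$children) == 0L)

#' Does the tree contain polytomies?
#'
#' A polytomy is an internal node with three or more children; a lineage tree
#' is completely resolved iff it has none.
#'
#' @param tree a `lineage_tree`.
#' @return Logical flag.
#' @export
has_polytomies <- function(tree) any(lengths(tree$children) >= 3L)

#' Node depths (divisions from the root)
#'
#' Depth counts edges from the root: the root has depth 0, its daughters
#' depth 1, and so on — the number of divisions separating a cell from the
#' founder.
#'
#' @param tree a `lineage_tree`.
#' @return Named integer vector over all node labels.
#' @export
node_depths <- function(tree) {
  n <- length(tree$labels)
  depth <- integer(n)
  for (i in bfs_order(tree)) {
    p <- tree$parent[i]
    depth[i] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  stats::setNames(depth, tree$labels)
}

# Breadth-first node order from the root; within a level, parents are visited
# in queue order and children in their stored (input) order.
bfs_order <- function(tree) {
  n <- length(tree$labels)
  order <- integer(n)
  order[1L] <- tree$root
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    i <- order[head]
    head <- head + 1L
    kids <- tree$children[[i]]
    if (length(kids)) {
      order[(tail + 1L):(tail + length(kids))] <- kids
      tail <- tail + length(kids)
    }
  }
  order
}

# Depth-first preorder (children in stored order); used for layouts and
# serialization so output order is deterministic.
dfs_order <- function(tree, start = tree$root) {
  out <- integer(0)
  stack <- start
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, i)
    stack <- c(stack, rev(tree$children[[i]]))
  }
  out
}

# Extract the subtree rooted at `node` (index), preserving labels, child
# order and branch lengths; the subtree root keeps its branch length in
# relative/absolute mode.
subtree_at <- function(tree, node) {
  keep <- dfs_order(tree, node)
  remap <- integer(length(tree$labels))
  remap[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent <- ifelse(keep == node, NA_integer_, remap[parent])
  bl <- if (is.null(tree$branch_length)) NULL else tree$branch_length[keep]
  lineage_tree(tree$labels[keep], parent, bl, tree$bl_mode)
}

# Canonical form used for isomorphism checks: sorts children recursively by
# their serialized form, so two trees are isomorphic (same labels, topology
# and lengths, ignoring child order) iff canonical strings are equal.
canonical_string <- function(tree, node = tree$root) {
  bl <- if (is.null(tree$branch_length)) "" else {
    b <- tree$branch_length[node]
    if (is.na(b)) "" else paste0(":", format(b, digits = 12))
  }
  kids <- tree$children[[node]]
  if (!length(kids)) return(paste0(tree$labels[node], bl))
  parts <- sort(vapply(kids, function(k) canonical_string(tree, k), character(1)))
  paste0("(", paste(parts, collapse = ","), ")", tree$labels[node], bl)
}

#' Test two lineage trees for isomorphism
#'
#' Trees are isomorphic when they have the same labelled topology and the
#' same branch lengths, ignoring the order of children at each node.
#'
#' @param a,b `lineage_tree` objects.
#' @return Logical flag.
#' @export
trees_isomorphic <- function(a, b) {
  identical(canonical_string(a), canonical_string(b))
}
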