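# Independent brute-force oracles and random-tree generators used across the
# suite.  The oracles deliberately avoid the package's own traversal code:
# they work directly on the parent vector of a tree by naive recursion or
# exhaustive enumeration.

# Random rooted tree built by repeated leaf splitting.  Returns a
# lineage_tree; all nodes labelled, optional polytomies and branch lengths.
rand_tree <- function(n_leaves, seed, polytomy_prob = 0, with_bl = FALSE,
                      bl_mode = "relative") {
  set.seed(seed)
  labels <- "n1"
  parent <- NA_integer_
  leaves <- 1L
  counter <- 1L
  while (length(leaves) < n_leaves) {
    split <- leaves[sample.int(length(leaves), 1L)]
    k <- if (stats::runif(1) < polytomy_prob) {
      sample(3:4, 1L)
    } else 2L
    k <- min(k, n_leaves - length(leaves) + 1L)
    if (k < 2L) k <- 2L
    kids <- integer(k)
    for (d in seq_len(k)) {
      counter <- counter + 1L
      labels <- c(labels, paste0("n", counter))
      parent <- c(parent, split)
      kids[d] <- length(labels)
    }
    leaves <- c(setdiff(leaves, split), kids)
  }
  bl <- NULL
  if (with_bl) {
    bl <- stats::runif(length(labels), 0.1, 2)
    bl[1L] <- 0
  }
  tr <- lineagelink::lineage_tree(labels, parent, bl,
                                  if (with_bl) "relative" else "none")
  if (with_bl && bl_mode == "absolute") {
    tr <- lineagelink::convert_bl_mode(tr, "absolute")
  }
  tr
}

# Naive recursive leaf enumeration under a node label.
oracle_clone <- function(tree, label) {
  i <- match(label, tree$labels)
  kids <- which(tree$parent == i)
  if (!length(kids)) return(tree$labels[i])
  unlist(lapply(tree$labels[kids], function(k) oracle_clone(tree, k)))
}

# Depth by walking parent pointers.
oracle_depth <- function(tree, label) {
  i <- match(label, tree$labels)
  d <- 0L
  while (!is.na(tree$parent[i])) {
    i <- tree$parent[i]
    d <- d + 1L
  }
  d
}

# Ancestor label set (self included), root last.
oracle_ancestors <- function(tree, label) {
  i <- match(label, tree$labels)
  out <- tree$labels[i]
  while (!is.na(tree$parent[i])) {
    i <- tree$parent[i]
    out <- c(out, tree$labels[i])
  }
  out
}

# MRCA by intersecting full ancestor sets; deepest common member.
oracle_mrca <- function(tree, a, b) {
  common <- intersect(oracle_ancestors(tree, a), oracle_ancestors(tree, b))
  depths <- vapply(common, function(l) oracle_depth(tree, l), integer(1))
  common[which.max(depths)]
}

# Level-k cut by naive per-leaf ancestor walk: every leaf is assigned to its
# ancestor at depth k (or itself if shallower).
oracle_depth_cut <- function(tree, k) {
  leaves <- tree$labels[!(seq_along(tree$labels) %in% tree$parent)]
  founder <- vapply(leaves, function(l) {
    anc <- rev(oracle_ancestors(tree, l))  # root first
    if (length(anc) > k) anc[k + 1L] else l
  }, character(1))
  split(leaves, founder)
}

# Time cut by naive per-leaf walk over node times: a leaf belongs to its
# shallowest ancestor whose time is >= t (or to itself when it terminated
# before t); at t <= root time everything is one root group.
oracle_time_cut <- function(tree, t) {
  times <- lineagelink::node_times(tree)
  leaves <- tree$labels[!(seq_along(tree$labels) %in% tree$parent)]
  root <- tree$labels[is.na(tree$parent)]
  if (t <= times[[root]]) return(split(leaves, rep(root, length(leaves))))
  founder <- vapply(leaves, function(l) {
    anc <- rev(oracle_ancestors(tree, l))  # root ... leaf
    hit <- anc[times[anc] >= t]
    if (length(hit)) hit[1L] else l  # terminated leaf persists
  }, character(1))
  split(leaves, founder)
}

# Compare a clone_partition against a named list of groups.
expect_same_partition <- function(partition, oracle_groups) {
  got <- lapply(partition$groups, function(g) sort(g))
  want <- lapply(oracle_groups, function(g) sort(unname(g)))
  expect_setequal(names(got), names(want))
  for (f in names(want)) expect_identical(got[[f]], want[[f]])
}

# Independent Newick writer for parser cross-checks (never uses to_newick).
rand_newick <- function(tree) {
  ser <- function(i) {
    kids <- which(tree$parent == i)
    bl <- if (is.null(tree$branch_length)) "" else
      paste0(":", format(tree$branch_length[i], digits = 10))
    if (!length(kids)) return(paste0(tree$labels[i], bl))
    paste0("(", paste(vapply(kids, ser, character(1)), collapse = ","), ")",
           tree$labels[i], bl)
  }
  paste0(ser(which(is.na(tree$parent))), ";")
}

# Tiny hand-rolled MaMuT-style XML for import tests.
mamut_xml_fixture <- function() {
  paste0(
    '<?xml version="1.0"?><TrackMate><Model><AllSpots>',
    '<SpotsInFrame frame="0">',
    '<Spot ID="1" name="root" FRAME="0" POSITION_X="0" POSITION_Y="0" POSITION_Z="0" />',
    '</SpotsInFrame>',
    paste0(vapply(1:3, function(f) paste0(
      '<SpotsInFrame frame="', f, '">',
      '<Spot ID="', 10 + f, '" FRAME="', f, '" POSITION_X="', f,
      '" POSITION_Y="0" POSITION_Z="0" />',
      '<Spot ID="', 20 + f, '" FRAME="', f, '" POSITION_X="-', f,
      '" POSITION_Y="1" POSITION_Z="0" />',
      '</SpotsInFrame>'), character(1)), collapse = ""),
    '</AllSpots><AllTracks><Track TRACK_ID="0">',
    '<Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="11" />',
    '<Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="21" />',
    '<Edge SPOT_SOURCE_ID="11" SPOT_TARGET_ID="12" />',
    '<Edge SPOT_SOURCE_ID="12" SPOT_TARGET_ID="13" />',
    '<Edge SPOT_SOURCE_ID="21" SPOT_TARGET_ID="22" />',
    '<Edge SPOT_SOURCE_ID="22" SPOT_TARGET_ID="23" />',
    '</Track></AllTracks></Model></TrackMate>')
}
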