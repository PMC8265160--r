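complete_binary <- function(depth) {
  # labels: b1 (root), b2.., breadth-first
  n <- 2^(depth + 1L) - 1L
  parent <- c(NA_integer_, rep(seq_len(n), each = 2L)[seq_len(n - 1L)])
  lineage_tree(paste0("b", seq_len(n)), parent)
}

test_that("clone extraction equals brute-force leaf enumeration", {
  tr <- parse_newick("((A,B)ab,C)r;")
  expect_setequal(clone_cells(tr, "r"), c("A", "B", "C"))
  expect_identical(clone_cells(tr, "C"), "C")
  expect_setequal(clone_cells(tr, "ab"), c("A", "B"))
  expect_error(clone_cells(tr, "nope"), "unknown")
  for (seed in 1:25) {
    rt <- rand_tree(sample(2:60, 1L), seed = seed, polytomy_prob = 0.25)
    node <- sample(rt$labels, 1L)
    expect_setequal(clone_cells(rt, node), oracle_clone(rt, node))
  }
})

test_that("descendant summaries count clone members and positioned cells", {
  tr <- parse_newick("((A,B)ab,C)r;")
  cells <- read_coordinates("cell,X,Y,Z\nA,0,0,0\nC,1,1,1")
  j <- suppressWarnings(join_cells(tr, cells))
  leafA <- descendant_summary(tr, "A", j)
  expect_identical(leafA$total_descendants, 1L)
  expect_identical(leafA$on_viewer_descendants, 1L)
  sub <- descendant_summary(tr, "ab", j)
  expect_identical(sub$total_descendants, 2L)
  expect_identical(sub$on_viewer_descendants, 1L)  # B has no coordinates
  expect_identical(descendant_summary(tr, "B", j)$on_viewer_descendants, 0L)
  expect_identical(descendant_summary(tr, "r", NULL)$on_viewer_descendants, 0L)
})

test_that("division-depth cuts partition the cells", {
  cb <- complete_binary(3L)  # 8 leaves
  p1 <- clones_at_division_depth(cb, 1L)
  expect_length(p1$groups, 2L)
  expect_identical(unname(lengths(p1$groups)), c(4L, 4L))
  p0 <- clones_at_division_depth(cb, 0L)
  expect_length(p0$groups, 1L)
  deep <- clones_at_division_depth(cb, 10L)
  expect_length(deep$groups, n_leaves(cb))
  expect_true(all(lengths(deep$groups) == 1L))
  expect_error(clones_at_division_depth(cb, -1), "integer")
  for (seed in 1:25) {
    rt <- rand_tree(sample(2:60, 1L), seed = seed + 50L, polytomy_prob = 0.3)
    k <- sample(0:6, 1L)
    expect_same_partition(clones_at_division_depth(rt, k),
                          oracle_depth_cut(rt, k))
  }
})

test_that("time cuts follow the edge-crossing rule with persistent leaves", {
  tr <- parse_newick("((A:1,B:2):1,C:3);", bl_mode = "relative")
  expect_length(clones_at_time(tr, 0)$groups, 1L)       # the root clone
  expect_length(clones_at_time(tr, 0.5)$groups, 2L)     # two daughter edges
  late <- clones_at_time(tr, 99)
  expect_length(late$groups, 3L)                        # singleton per leaf
  expect_true(all(lengths(late$groups) == 1L))
  # A terminates at time 2; at t = 2.5 it persists as its own clone
  mid <- clones_at_time(tr, 2.5)
  expect_true("A" %in% names(mid$groups))
  expect_error(clones_at_time(parse_newick("(A,B);"), 1), "branch lengths")
  for (seed in 1:25) {
    rt <- rand_tree(sample(2:50, 1L), seed = seed + 80L, with_bl = TRUE)
    t <- stats::runif(1, 0, max(node_times(rt)) * 1.2)
    expect_same_partition(clones_at_time(rt, t), oracle_time_cut(rt, t))
  }
})

test_that("cut groups are pairwise disjoint and cover the leaf set", {
  for (seed in 1:20) {
    rt <- rand_tree(sample(3:60, 1L), seed = seed + 200L, polytomy_prob = 0.3,
                    with_bl = TRUE)
    for (part in list(clones_at_division_depth(rt, sample(0:5, 1L)),
                      clones_at_time(rt, stats::runif(1, 0, max(node_times(rt)))))) {
      members <- unlist(part$groups, use.names = FALSE)
      expect_identical(anyDuplicated(members), 0L)
      expect_setequal(members, leaf_labels(rt))
    }
  }
})

test_that("mrca matches ancestor-set intersection", {
  tr <- parse_newick("((A,B)ab,C)r;")
  expect_identical(mrca(tr, "A", "A"), "A")
  expect_identical(mrca(tr, "A", "B"), "ab")
  expect_identical(mrca(tr, "A", "C"), "r")
  expect_identical(mrca(tr, "ab", "A"), "ab")  # a node is its own ancestor
  for (seed in 1:20) {
    rt <- rand_tree(sample(3:50, 1L), seed = seed + 300L, polytomy_prob = 0.2)
    pair <- sample(rt$labels, 2L)
    expect_identical(mrca(rt, pair[1L], pair[2L]),
                     oracle_mrca(rt, pair[1L], pair[2L]))
  }
})

test_that("relationship levels are MRCA depths and nest into clones", {
  tr <- parse_newick("((A,B),C);")
  rm <- relationship_levels(tr, "A")
  expect_identical(rm$level[["A"]], 2L)  # own depth
  expect_identical(rm$level[["B"]], 1L)
  expect_identical(rm$level[["C"]], 0L)
  expect_error(relationship_levels(tr, "_n2"), "not a leaf")
  expect_error(relationship_levels(tr, "zz"), "unknown")
  for (seed in 1:15) {
    rt <- rand_tree(sample(3:50, 1L), seed = seed + 400L, polytomy_prob = 0.2)
    focal <- sample(leaf_labels(rt), 1L)
    rm <- relationship_levels(rt, focal)
    depth_f <- oracle_depth(rt, focal)
    expect_identical(rm$level[[focal]], depth_f)
    # quadratic oracle over all leaves
    for (leaf in names(rm$level)) {
      expect_identical(rm$level[[leaf]],
                       oracle_depth(rt, oracle_mrca(rt, focal, leaf)))
    }
    # nested-clone law: cells at level >= L are the clone of the depth-L
    # ancestor of the focal cell
    anc <- rev(oracle_ancestors(rt, focal))  # root first
    for (L in seq.int(0L, depth_f)) {
      expect_setequal(names(rm$level)[rm$level >= L],
                      clone_cells(rt, anc[L + 1L]))
    }
  }
})

test_that("lineage paths run root to cell along parent edges", {
  tr <- parse_newick("((A,B)ab,C)r;")
  expect_identical(lineage_path(tr, "r"), "r")
  expect_identical(lineage_path(tr, "A"), c("r", "ab", "A"))
  for (seed in 1:10) {
    rt <- rand_tree(sample(3:40, 1L), seed = seed + 600L)
    cell <- sample(rt$labels, 1L)
    path <- lineage_path(rt, cell)
    expect_identical(path, rev(oracle_ancestors(rt, cell)))
    expect_length(path, oracle_depth(rt, cell) + 1L)
  }
})

test_that("collapse/expand/prune are idempotent overlays on an immutable tree", {
  tr <- parse_newick("((A,B)ab,(C,D)cd)r;")
  before <- to_newick(tr)
  v0 <- view_state()
  v1 <- collapse_node(tr, v0, "ab")
  expect_identical(expand_node(tr, v1, "ab"), v0)        # expand o collapse = id
  expect_identical(collapse_node(tr, v1, "ab"), v1)      # idempotent
  expect_error(collapse_node(tr, v0, "A"), "leaf")
  expect_error(prune_node(tr, v0, "r"), "root")
  v2 <- prune_node(tr, v0, "cd")
  expect_identical(unprune_node(tr, v2, "cd"), v0)
  # collapsed and pruned sets stay disjoint
  v3 <- prune_node(tr, v1, "ab")
  expect_false("ab" %in% v3$collapsed)
  # pruning removes exactly the clone from the displayed leaves
  dt <- displayed_tree(tr, v2)
  expect_setequal(leaf_labels(dt), c("A", "B"))
  expect_identical(n_leaves(dt), n_leaves(tr) - length(clone_cells(tr, "cd")))
  vleaf <- prune_node(tr, v0, "D")
  expect_identical(n_leaves(displayed_tree(tr, vleaf)), 3L)
  expect_identical(to_newick(tr), before)  # underlying tree untouched
})

test_that("clone export round-trips through the JSON reader", {
  tr <- parse_newick("((A:1,B:2)ab:1,C:3)r:0;", bl_mode = "relative")
  whole <- parse_json_tree(export_clone(tr, "r"), bl_mode = "relative")
  expect_true(trees_isomorphic(whole, tr))
  single <- parse_json_tree(export_clone(tr, "A"), bl_mode = "relative")
  expect_identical(n_leaves(single), 1L)
  expect_identical(leaf_labels(single), "A")
  for (seed in 1:10) {
    rt <- rand_tree(sample(3:40, 1L), seed = seed + 700L, with_bl = TRUE)
    node <- sample(rt$labels, 1L)
    back <- parse_json_tree(export_clone(rt, node), bl_mode = "relative")
    expect_setequal(leaf_labels(back), oracle_clone(rt, node))
  }
})

test_that("branch subsetting caps polytomous trees and spares resolved ones", {
  resolved <- rand_tree(600, seed = 9, polytomy_prob = 0)
  out <- subset_branches(resolved)
  expect_false(out$report$applied)
  expect_identical(out$report$reason, "not applicable")
  expect_true(trees_isomorphic(out$tree, resolved))

  small <- rand_tree(400, seed = 10, polytomy_prob = 0.3)
  out2 <- subset_branches(small)
  expect_false(out2$report$applied)
  expect_identical(out2$report$reason, "not needed")

  star <- lineage_tree(c("r", sprintf("L%04d", 1:2000)), c(NA, rep(1L, 2000)))
  out3 <- subset_branches(star)
  expect_true(out3$report$applied)
  expect_lte(n_leaves(out3$tree), 500L)
  expect_identical(out3$report$hidden_cells, 1500L)
  expect_identical(unname(out3$report$hidden_per_polytomy), 1500L)
  # deterministic: kept children are the label-sorted first block
  expect_identical(leaf_labels(out3$tree), sprintf("L%04d", 1:500))
  out3b <- subset_branches(star)
  expect_true(trees_isomorphic(out3$tree, out3b$tree))

  poly <- rand_tree(900, seed = 11, polytomy_prob = 0.5)
  out4 <- subset_branches(poly)
  expect_true(out4$report$applied)
  expect_lte(n_leaves(out4$tree), 900L)
  expect_identical(n_leaves(out4$tree) + out4$report$hidden_cells,
                   n_leaves(poly))
})

test_that("cut and relationship outputs reload as annotation tables", {
  tr <- parse_newick("((A,B)ab,(C,D)cd)r;")
  csv <- partition_to_csv(clones_at_division_depth(tr, 1L))
  ann <- read_annotations(csv)
  expect_setequal(ann$cell, c("A", "B", "C", "D"))
  expect_identical(sort(unique(ann$annotation)), c("ab", "cd"))
  csv2 <- partition_to_csv(relationship_levels(tr, "A"))
  ann2 <- read_annotations(csv2)
  expect_identical(ann2$annotation[ann2$cell == "A"], "2")
})
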