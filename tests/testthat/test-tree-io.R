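test_that("format detection distinguishes Newick from JSON", {
  expect_identical(detect_tree_format("((A,B),C);"), "newick")
  expect_identical(detect_tree_format('{"name":"r","children":[{"name":"A"}]}'),
                   "json")
  expect_identical(detect_tree_format("  \n((A,B),C);"), "newick")
  expect_identical(detect_tree_format("A;"), "newick")
  expect_error(detect_tree_format("not a tree at all"), "unrecognizable")
  expect_error(detect_tree_format("   "), "empty")
})

test_that("basic Newick topologies parse with correct shape", {
  tr <- parse_newick("((A,B),C);")
  expect_identical(n_leaves(tr), 3L)
  expect_setequal(leaf_labels(tr), c("A", "B", "C"))
  expect_length(tr$children[[tr$root]], 2L)
  expect_identical(tr$bl_mode, "none")
  expect_null(tr$branch_length)
})

test_that("relative branch lengths accumulate into node times", {
  tr <- parse_newick("((A:1,B:2):1,C:3);", bl_mode = "relative")
  tm <- node_times(tr)
  expect_equal(tm[["A"]], 2)
  expect_equal(tm[["B"]], 3)
  expect_equal(tm[["C"]], 3)
  expect_equal(unname(tm[tr$labels[tr$root]]), 0)
})

test_that("quoted labels, underscores and comments survive parsing", {
  tr <- parse_newick("('a b',c_d)[a comment]root;")
  expect_setequal(leaf_labels(tr), c("a b", "c_d"))
  expect_identical(tr$labels[tr$root], "root")
  tr2 <- parse_newick("('it''s',B)r;")
  expect_true("it's" %in% leaf_labels(tr2))
  # quoting round-trips through the writer
  expect_true(trees_isomorphic(tr2, parse_newick(to_newick(tr2))))
})

test_that("unlabeled internal nodes are auto-named breadth-first", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_identical(tr$labels[tr$root], "_n1")
  depth <- node_depths(tr)
  auto <- grep("^_n", tr$labels, value = TRUE)
  expect_identical(sort(auto), c("_n1", "_n2", "_n3"))
  expect_identical(unname(depth[c("_n2", "_n3")]), c(1L, 1L))
  # auto-names never clash with explicit labels
  tr2 <- parse_newick("((A,B)_n1,C);")
  expect_identical(anyDuplicated(tr2$labels), 0L)
})

test_that("malformed Newick is rejected with a positioned error", {
  expect_error(parse_newick("((A,B),C;"), "position")
  expect_error(parse_newick("(A,B)));"), "position")
  expect_error(parse_newick("((A,B),A);"), "duplicate")
  expect_error(parse_newick("(A:1,B);", bl_mode = "relative"), "missing")
  expect_error(parse_newick("(A,B)r:xx;"), "position")
})

test_that("absolute lengths must not decrease toward the leaves", {
  expect_error(parse_newick("((A:5,B:2):3,C:4);", bl_mode = "absolute"),
               "decrease")
  tr <- parse_newick("((A:5,B:6):3,C:4);", bl_mode = "absolute")
  expect_equal(node_times(tr)[["A"]], 5)
  expect_equal(unname(node_times(tr)[tr$labels[tr$root]]), 0)
})

test_that("lengths in the file are discarded with a warning when bl_mode is none", {
  expect_warning(tr <- parse_newick("((A:1,B:2):1,C:3);", bl_mode = "none"),
                 "discarded")
  expect_null(tr$branch_length)
  expect_identical(tr$bl_mode, "none")
})

test_that("JSON lineage schema parses and rejects malformed nodes", {
  tr <- parse_json_tree('{"name":"r","children":[{"name":"A"},{"name":"B"}]}')
  expect_identical(n_leaves(tr), 2L)
  expect_identical(tr$labels[tr$root], "r")
  expect_error(parse_json_tree('{"children":[{"name":"A"}]}'), "name")
  expect_warning(
    parse_json_tree('{"name":"r","colour":"red","children":[{"name":"A"},{"name":"B"}]}'),
    "unknown JSON keys")
})

test_that("Newick and JSON encodings of one topology parse isomorphically", {
  for (seed in 1:20) {
    tr <- rand_tree(sample(2:40, 1L), seed = seed, polytomy_prob = 0.2,
                    with_bl = TRUE)
    from_nwk <- parse_newick(to_newick(tr), bl_mode = "relative")
    from_json <- parse_json_tree(to_json(tr), bl_mode = "relative")
    expect_true(trees_isomorphic(from_nwk, from_json))
    expect_true(trees_isomorphic(from_nwk, tr))
  }
})

test_that("write-parse round trips are the identity, both formats, all modes", {
  one <- lineage_tree("A", NA_integer_)
  expect_identical(to_newick(one), "A;")
  for (seed in 1:15) {
    n <- sample(2:60, 1L)
    trn <- rand_tree(n, seed = seed, polytomy_prob = 0.3)
    expect_true(trees_isomorphic(trn, parse_newick(to_newick(trn))))
    expect_true(trees_isomorphic(trn, parse_json_tree(to_json(trn))))
    trr <- rand_tree(n, seed = seed + 100L, with_bl = TRUE)
    expect_true(trees_isomorphic(trr, parse_newick(to_newick(trr), "relative")))
    tra <- convert_bl_mode(trr, "absolute")
    expect_true(trees_isomorphic(tra, parse_newick(to_newick(tra), "absolute")))
    expect_true(trees_isomorphic(tra, parse_json_tree(to_json(tra), "absolute")))
  }
  # 200-node tree round trip: parse(write(parse(x))) isomorphic to parse(x)
  big <- rand_tree(100, seed = 42, polytomy_prob = 0.2, with_bl = TRUE)
  p1 <- parse_newick(to_newick(big), "relative")
  expect_true(trees_isomorphic(p1, parse_newick(to_newick(p1), "relative")))
})

test_that("branch-length mode conversion preserves node times and inverts", {
  chain <- parse_newick("(((D:3)C:2)B:1)A:1;", bl_mode = "relative")
  abs <- convert_bl_mode(chain, "absolute")
  expect_equal(unname(abs$branch_length[match(c("A", "B", "C", "D"), abs$labels)]),
               c(1, 2, 4, 7))
  for (seed in 1:15) {
    tr <- rand_tree(sample(2:50, 1L), seed = seed, with_bl = TRUE)
    abs <- convert_bl_mode(tr, "absolute")
    expect_equal(node_times(abs), node_times(tr), tolerance = 1e-12)
    back <- convert_bl_mode(abs, "relative")
    expect_equal(back$branch_length, tr$branch_length, tolerance = 1e-9)
    # times monotone non-decreasing along root->leaf paths
    tm <- node_times(tr)
    for (i in seq_along(tr$labels)) {
      p <- tr$parent[i]
      if (!is.na(p)) expect_gte(tm[[i]], tm[[p]])
    }
  }
  expect_error(node_times(parse_newick("(A,B);")), "branch lengths")
  expect_error(convert_bl_mode(parse_newick("(A,B);"), "absolute"),
               "no branch lengths")
})

test_that("parser agrees with the ape reference parser on a corpus", {
  skip_if_not_installed("ape")
  for (seed in 1:25) {
    tr <- rand_tree(sample(3:50, 1L), seed = seed + 500L,
                    polytomy_prob = 0.25, with_bl = TRUE)
    nwk <- rand_newick(tr)  # helper writer, independent of to_newick()
    mine <- parse_newick(nwk, bl_mode = "relative")
    ref <- ape::read.tree(text = nwk)
    expect_setequal(leaf_labels(mine), ref$tip.label)
    # parent map equality over all labelled nodes
    ref_labels <- c(ref$tip.label, ref$node.label)
    ref_parent <- stats::setNames(ref_labels[ref$edge[, 1L]],
                                  ref_labels[ref$edge[, 2L]])
    for (lab in names(ref_parent)) {
      i <- match(lab, mine$labels)
      expect_identical(mine$labels[mine$parent[i]], unname(ref_parent[lab]))
    }
    # branch lengths agree edge-wise
    ref_bl <- stats::setNames(ref$edge.length, ref_labels[ref$edge[, 2L]])
    for (lab in names(ref_bl)) {
      expect_equal(mine$branch_length[match(lab, mine$labels)],
                   unname(ref_bl[lab]), tolerance = 1e-8)
    }
  }
})

test_that("validation reports collect structured messages", {
  rep <- validate_tree_text("((A,B),C);")
  expect_true(rep$parse_ok)
  expect_identical(rep$format, "newick")
  expect_identical(rep$n_cells, 3L)
  expect_identical(rep$n_nodes, 5L)
  expect_false(rep$has_polytomies)
  bad <- validate_tree_text("((A,B),A);")
  expect_false(bad$parse_ok)
  expect_true(any(bad$messages$severity == "error"))
  warned <- validate_tree_text("((A:1,B:1):1,C:2);", bl_mode = "none")
  expect_true(warned$parse_ok)
  expect_true(any(warned$messages$severity == "warning"))
  js <- report_to_json(rep)
  expect_true(jsonlite::validate(js))
  expect_identical(jsonlite::fromJSON(js)$n_cells, 3L)
})
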