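test_that("Newick parsing validates structure and flags polytomies", {
  phy <- parse_tree("((A:0.1,B:0.3):0.2,C:0.5);")
  expect_equal(length(phy$tip.label) + phy$Nnode, 5)
  expect_equal(nrow(phy$edge), 4)
  root <- length(phy$tip.label) + 1L
  expect_equal(sum(phy$edge[, 1] == root), 2)

  expect_error(parse_tree("(A,B,C);", require_binary = TRUE), "polytom")
  expect_error(parse_tree("((A:0.1,A:0.3):0.2,C:0.5);"), "duplicate")
  expect_error(parse_tree("((A:0.1,B:-0.3):0.2,C:0.5);"), "negative")
})

test_that("Newick round-trip preserves topology and lengths", {
  phy <- rand_binary_tree(20, seed = 42)
  phy2 <- parse_tree(write_tree(phy))
  ev <- edge_vectors(phy, phy2, unrooted = FALSE)
  expect_equal(ev$a, ev$b, tolerance = 1e-10)
  expect_setequal(phy$tip.label, phy2$tip.label)
})

test_that("node-to-tip distances match closed forms and the all-paths oracle", {
  # cherry: mean of the two terminal branches
  phy <- parse_tree("(A:0.1,B:0.3);")
  d <- node_to_tip_distances(phy)
  expect_equal(unname(d[3]), 0.2)
  expect_equal(unname(d[1]), 0)

  # root of a 3-tip tree: all root-to-tip paths averaged
  phy3 <- parse_tree("((A:0.1,B:0.3):0.2,C:0.5);")
  d3 <- node_to_tip_distances(phy3)
  expect_equal(unname(d3[4]), (0.3 + 0.5 + 0.5) / 3)

  for (seed in 1:5) {
    phy <- rand_binary_tree(sample(4:12, 1), seed)
    expect_equal(unname(node_to_tip_distances(phy)), enum_node_to_tip(phy),
                 tolerance = 1e-12)
  }
})

test_that("root node-to-tip distance conserves the total path sum", {
  for (seed in 6:9) {
    phy <- rand_binary_tree(10, seed)
    d <- node_to_tip_distances(phy)
    root <- length(phy$tip.label) + 1L
    depths <- ape::node.depth.edgelength(phy)
    expect_equal(unname(d[root]) * length(phy$tip.label),
                 sum(depths[seq_len(length(phy$tip.label))]))
  }
})

test_that("depth classes partition internal nodes", {
  # cherry is terminal, root is deep
  phy <- parse_tree("(((A,B),(C,D)),(E,F));")
  phy$edge.length <- rep(1, nrow(phy$edge))
  cls <- classify_node_depth(phy)
  root <- length(phy$tip.label) + 1L
  expect_equal(cls$class[cls$node == root], "deep")
  cherry <- phy$edge[phy$edge[, 2] == 1, 1]
  expect_equal(cls$class[cls$node == cherry], "terminal")
  expect_true(all(cls$class %in% c("terminal", "intermediate", "deep")))
  expect_equal(nrow(cls), phy$Nnode)

  # 8-tip ladder: the deep non-root nodes are exactly those subtending
  # >= 4 tips (counts enumerated directly from the nesting)
  lad <- parse_tree("(((((((A,B),C),D),E),F),G),H);")
  cls2 <- classify_node_depth(lad)
  root2 <- 9L
  deep_nonroot <- cls2$node[cls2$class == "deep" & cls2$node != root2]
  expect_setequal(cls2$n_tips[cls2$node %in% deep_nonroot], c(7, 6, 5, 4))
  expect_equal(cls2$class[cls2$n_tips == 2 & cls2$node != root2][1], "terminal")

  expect_error(classify_node_depth(lad, deep_fraction = 0), "deep_fraction")
  expect_error(classify_node_depth(lad, deep_fraction = 1.2), "deep_fraction")

  for (seed in 11:15) {
    phy <- rand_binary_tree(sample(5:14, 1), seed)
    cls <- classify_node_depth(phy)
    expect_equal(sort(cls$node),
                 (length(phy$tip.label) + 1L):(length(phy$tip.label) + phy$Nnode))
    expect_false(anyNA(cls$class))
  }
})

test_that("edge vectors align by split and honor the unrooted view", {
  phy <- rand_binary_tree(5, seed = 21)
  ev <- edge_vectors(phy, phy)
  expect_equal(nrow(ev), 2 * 5 - 3)  # unrooted edge count
  expect_equal(ev$a, ev$b)
  expect_equal(nrow(edge_vectors(phy, phy, internal_only = TRUE)), 2)

  # scrambled tip order, same topology
  phy_b <- phy
  phy_b$edge.length <- phy$edge.length * 2
  ev2 <- edge_vectors(phy, phy_b)
  expect_equal(ev2$b, 2 * ev2$a)

  big <- rand_binary_tree(44, seed = 22)
  expect_equal(nrow(edge_vectors(big, big)), 85)  # 2n - 3 for n = 44

  other <- rand_binary_tree(5, seed = 23)
  expect_error(edge_vectors(phy, other), "topolog|tip sets")
})

test_that("time trees enforce age invariants", {
  phy <- parse_tree("((A:1,B:1):1,C:2);")
  tt <- as_time_tree(phy)
  expect_equal(tt$ages[4], 2)
  expect_true(all(branch_durations(tt) > 0))
  expect_error(time_tree(tt$phy, c(0, 0, 0, 1, 1.5)), "older")
  expect_error(time_tree(tt$phy, c(0, 0, 0.5, 2, 1)), "tip ages")
})

test_that("fitted unrooted lengths map back onto the rooted topology", {
  rooted <- rand_binary_tree(8, seed = 61)
  un <- ape::unroot(rooted)
  mapped <- map_to_rooted(un, rooted)
  expect_equal(sum(mapped$edge.length), sum(rooted$edge.length))
  # non-root node-to-tip distances are invariant to the root-edge split
  d_orig <- node_to_tip_distances(rooted)
  d_map <- node_to_tip_distances(mapped)
  root <- 9L
  nonroot <- setdiff(seq_along(d_orig), root)
  expect_equal(d_map[nonroot], d_orig[nonroot], tolerance = 1e-12)
})
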