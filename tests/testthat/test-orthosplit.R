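delim_map <- species_map_delimiter("_", 1, from_end = TRUE)

test_that("so_events classifies the textbook overlap case", {
  t <- parse_newick("((g1_X,g2_Y),(g3_X,g4_Y));")
  ev <- so_events(t, delim_map)
  root_row <- ev[ev$node == 5, ]
  expect_equal(root_row$event, "duplication")
  expect_equal(root_row$overlap_size, 2L)
  expect_equal(root_row$overlap_score, 1.0)
  expect_true(all(ev$event[ev$node != 5] == "speciation"))
})

test_that("single-copy families have no duplications and zero scores", {
  t <- parse_newick("((g1_X,g2_Y),(g3_Z,g4_W));")
  ev <- so_events(t, delim_map)
  expect_true(all(ev$event == "speciation"))
  expect_true(all(ev$overlap_score == 0))
})

test_that("so_events matches an independent set-arithmetic oracle", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  st <- example_dated_species_tree()
  for (i in 1:30) {
    sim <- simulate_family(st, sim_params(0.3, 0.1, 0), seed = 100 + i)
    if (sim$extinct || length(sim$observable_tree$tip.label) < 3) next
    phy <- sim$observable_tree
    phy$node.label <- NULL
    sp <- map_species(phy, sim$species_map)
    ev <- so_events(phy, sim$species_map)
    ref <- so_oracle(phy, sp)
    ord <- order(ev$node)
    expect_equal(ev$node[ord], ref$node)
    expect_equal(ev$overlap_size[ord], ref$overlap_size)
    expect_equal(ev$overlap_score[ord], ref$overlap_score)
    expect_equal(ev$event[ord], ref$event)
  }
})

test_that("paralog-generating detection follows the min_common rule", {
  t <- parse_newick("((g1_X,g2_Y),(g3_X,g4_Y));")
  fl <- find_paralog_generating(t, delim_map, min_common = 2)
  expect_equal(fl$node, 5L)
  expect_true(all(fl$paralog_generating))
  # overlap of one species only: nothing flagged at min_common = 2
  t2 <- parse_newick("((g1_X,g2_Y),(g3_X,g4_Z));")
  expect_equal(nrow(find_paralog_generating(t2, delim_map, 2)), 0L)
  # ... but flagged at min_common = 1 (plain SO duplication)
  fl1 <- find_paralog_generating(t2, delim_map, 1)
  ev <- so_events(t2, delim_map)
  expect_setequal(fl1$node, ev$node[ev$event == "duplication"])
})

test_that("raising min_common never flags more nodes", {
  set.seed(23)
  st <- example_dated_species_tree()
  for (i in 1:10) {
    sim <- simulate_family(st, sim_params(0.4, 0.1, 0), seed = 300 + i)
    if (sim$extinct || length(sim$observable_tree$tip.label) < 3) next
    counts <- vapply(1:4, function(mc)
      nrow(find_paralog_generating(sim$observable_tree, sim$species_map, mc)),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("split_at_nodes releases child subtrees and partitions leaves", {
  t <- parse_newick("((g1_X,g2_Y),(g3_X,g4_Y));")
  sets <- split_at_nodes(t, 5L)  # root
  expect_length(sets, 2L)
  expect_setequal(sets[[1]]$labels, c("g1_X", "g2_Y"))
  expect_setequal(sets[[2]]$labels, c("g3_X", "g4_Y"))
  # no flagged nodes: identity
  sets0 <- extract_ortholog_sets(parse_newick("((g1_X,g2_Y),g3_Z);"),
                                 delim_map, 2)
  expect_length(sets0, 1L)
  expect_equal(sets0[[1]]$provenance, "root")
  expect_error(split_at_nodes(t, 99L), "not an internal node")
})

test_that("splitting below the root keeps a residual part", {
  # flagged node is internal: its children are released, the rest remains
  t <- parse_newick("(((g1_X,g2_X),g3_Y),(g4_Z,g5_W));")
  ev <- so_events(t, delim_map)
  dup <- ev$node[ev$event == "duplication"]
  expect_length(dup, 1L)
  sets <- split_at_nodes(t, dup)
  expect_length(sets, 3L)
  provs <- vapply(sets, `[[`, character(1), "provenance")
  expect_true("root" %in% provs)
  sizes <- sort(vapply(sets, `[[`, integer(1), "size"))
  expect_equal(sizes, c(1L, 1L, 3L))
  all_labels <- sort(unlist(lapply(sets, `[[`, "labels")))
  expect_equal(all_labels, sort(t$tip.label))
})

test_that("nested flagged nodes are dissolved root-first", {
  t <- parse_newick("(((g1_X,g2_Y),(g3_X,g4_Y)),(g5_X,g6_Y));")
  fl <- find_paralog_generating(t, delim_map, 2)
  expect_equal(nrow(fl), 2L)  # root and the inner duplication
  sets <- extract_ortholog_sets(t, delim_map, 2)
  expect_length(sets, 3L)
  got <- sort(vapply(sets, function(s)
    paste(sort(s$labels), collapse = ","), character(1)))
  expect_equal(got, c("g1_X,g2_Y", "g3_X,g4_Y", "g5_X,g6_Y"))
})

test_that("ortholog sets always partition the leaf set", {
  set.seed(31)
  st <- example_dated_species_tree()
  for (i in 1:20) {
    sim <- simulate_family(st, sim_params(0.4, 0.15, 0), seed = 500 + i)
    if (sim$extinct) next
    sets <- extract_ortholog_sets(sim$observable_tree, sim$species_map, 2)
    labels <- unlist(lapply(sets, `[[`, "labels"))
    expect_equal(sort(labels), sort(sim$observable_tree$tip.label))
    expect_equal(anyDuplicated(labels), 0L)
    for (s in sets) expect_setequal(s$labels, s$tree$tip.label)
  }
})

test_that("flagged nodes on simulations are true duplications", {
  # with transfers off, a node whose child subtrees share >= 2 species can
  # only have arisen by duplication; check against the simulator's node
  # annotations carried through pruning
  st <- example_dated_species_tree()
  n_flagged <- 0L
  for (i in 1:40) {
    sim <- simulate_family(st, sim_params(), seed = 700 + i)
    if (sim$extinct || length(sim$observable_tree$tip.label) < 3) next
    obs <- sim$observable_tree
    fl <- find_paralog_generating(obs, sim$species_map, 2)
    if (nrow(fl) == 0) next
    ntip <- length(obs$tip.label)
    ann <- obs$node.label[fl$node - ntip]
    expect_true(all(ann == "D"))
    n_flagged <- n_flagged + nrow(fl)
  }
  expect_gt(n_flagged, 0L)
})

test_that("split then graft restores the original family tree", {
  t <- parse_newick("(((g1_X:1,g2_Y:1):1,(g3_X:1,g4_Y:1):1):1,g5_Z:3);")
  fl <- find_paralog_generating(t, delim_map, 2)
  sets <- split_at_nodes(t, fl$node)
  sub_sets <- Filter(function(s) s$provenance != "root", sets)
  back <- graft_orthologs(t, lapply(sub_sets, `[[`, "tree"),
                          vapply(sub_sets, `[[`, character(1), "provenance"))
  expect_identical(canonical_topology(back), canonical_topology(t))
  expect_setequal(back$tip.label, t$tip.label)
})

test_that("graft rejects subtrees with mismatched leaf sets", {
  t <- parse_newick("((g1_X,g2_Y),(g3_X,g4_Y));")
  sets <- split_at_nodes(t, 5L)
  bad <- sets[[1]]$tree
  bad$tip.label[1] <- "renamed"
  expect_error(
    graft_orthologs(t, list(bad), sets[[1]]$provenance),
    "leaf-set mismatch")
})

test_that("grafting re-estimated subtrees preserves per-set restrictions", {
  t <- parse_newick(
    "(((g1_X,g2_Y),(g3_Z,g4_W)),((g5_X,g6_Y),(g7_Z,g8_W)));")
  sets <- split_at_nodes(t, 9L)  # root duplication
  # "re-estimate": a different topology over the same leaves
  re1 <- parse_newick("((g1_X,g3_Z),(g2_Y,g4_W));")
  back <- graft_orthologs(t, list(re1), sets[[1]]$provenance)
  expect_setequal(back$tip.label, t$tip.label)
  sub <- prune_to_leafset(back, re1$tip.label)
  expect_identical(canonical_topology(sub), canonical_topology(re1))
})
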