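test_that("the sensitivity grid enumerates 16 labelled parameter sets", {
  g <- build_parameter_grid()
  expect_equal(nrow(g), 16)
  expect_true(all(c("1.A", "4.D") %in% g$label))
  expect_equal(anyDuplicated(g$label), 0)
  expect_equal(g$label[1:4], c("1.A", "1.B", "1.C", "1.D"))
  expect_setequal(g$weighting, 1:4)
  expect_setequal(g$rooting, c("A", "B", "C", "D"))
})

test_that("a noise-free scenario yields the true tree in every grid cell", {
  sc <- generate_scenario(n_taxa = 12, n_sources = 14, keep_fraction = 0.8,
                          n_nni = 0, alpha = Inf, seed = 19)
  sens <- run_sensitivity(sc$sources,
                          search_cfg = search_config(n_addition_replicates = 2,
                                                     swap = "spr", seed = 19))
  expect_length(sens, 16)
  for (cell in sens) {
    expect_equal(phangorn::RF.dist(cell$strict, sc$true_tree), 0)
    expect_equal(phangorn::RF.dist(cell$semistrict, sc$true_tree), 0)
  }
  # all 16 strict consensuses pairwise identical
  for (i in 1:15) {
    cmp <- spr_distance(sens[[i]]$strict, sens[[i + 1]]$strict)
    expect_equal(cmp$similarity_pct, 100)
  }
})

test_that("upweighted genetic partitions override conflicting language trees", {
  # genetic sources support the true tree; language trees support a
  # conflicting resolution of the same taxa
  tt <- as_rooted(ape::read.tree(text = "(((((A,B),C),D),E),F);"))
  conflict <- as_rooted(ape::read.tree(text = "(((((A,F),C),D),E),B);"))
  sources <- c(
    lapply(1:4, function(i)
      source_record(paste0("g", i), "tree", "genomic_tree", tt, rooted = TRUE)),
    lapply(1:3, function(i)
      source_record(paste0("l", i), "tree", "language_tree", conflict,
                    rooted = TRUE)))
  grid <- build_parameter_grid()
  sens <- run_sensitivity(sources, grid[grid$label %in% c("3.A", "4.A"), ],
                          search_cfg = search_config(n_addition_replicates = 4,
                                                     swap = "spr", seed = 3))
  for (cell in sens)
    expect_equal(phangorn::RF.dist(cell$strict, tt), 0)

  # deactivating the language partition reproduces the 1:1000 topology
  sens_d <- run_sensitivity(sources, grid[grid$label == "3.A", ],
                            search_cfg = search_config(n_addition_replicates = 4,
                                                       swap = "spr", seed = 3),
                            deactivate = TRUE)
  expect_equal(phangorn::RF.dist(sens_d[["3.A"]]$strict,
                                 sens[["3.A"]]$strict), 0)
})

test_that("a planted wandering rogue is uniquely flagged and pruning resolves", {
  backbone <- generate_true_tree(10, seed = 2)
  trees <- wandering_rogue_trees(backbone, c(2, 8, 14))
  wr <- identify_wildcards(trees, min_gain = 1, exclusion_threshold = 5)
  expect_length(wr$flagged, 1)
  expect_equal(wr$flagged[[1]]$taxa, "R")
  expect_gte(wr$flagged[[1]]$node_gain, 1)
  expect_gte(length(wr$flagged[[1]]$alternative_positions), 2)
  # pruned strict consensus recovers the clean backbone completely
  pc <- pruned_strict_consensus(trees, "R")
  expect_equal(phangorn::RF.dist(pc, backbone), 0)
  expect_equal(mrpsupertree:::n_resolved_nodes(pc),
               length(pc$tip.label) - 2)
})

test_that("identical trees produce an empty wildcard report", {
  tt <- random_rooted_tree(8)
  trees <- c(tt, tt, tt)
  class(trees) <- "multiPhylo"
  wr <- identify_wildcards(trees)
  expect_length(wr$flagged, 0)
  expect_length(wr$pruned_taxa, 0)
})

test_that("two independent rogues are both recovered with additive gain", {
  backbone <- generate_true_tree(12, seed = 5)
  with_r <- wandering_rogue_trees(backbone, c(2, 9, 16))
  # second rogue S wanders across the same trees at other edges
  trees <- lapply(seq_along(with_r), function(i) {
    tr <- with_r[[i]]
    as_rooted(mrpsupertree:::attach_leaf(tr, "S",
                                         tr$edge[c(4, 11, 19)[i], 2]))
  })
  class(trees) <- "multiPhylo"
  wr <- identify_wildcards(trees, min_gain = 1)
  flagged <- sort(unlist(lapply(wr$flagged, `[[`, "taxa")))
  expect_equal(flagged, c("R", "S"))
  # combined gain equals pruning both at once (brute force over the pair)
  both <- mrpsupertree:::prune_trees(trees, c("R", "S"))
  gain_both <- mrpsupertree:::n_resolved_nodes(strict_consensus(both)) -
    mrpsupertree:::n_resolved_nodes(
      ape::drop.tip(strict_consensus(trees), c("R", "S")))
  expect_equal(sum(vapply(wr$flagged, `[[`, 1L, "node_gain")), gain_both)
})

test_that("node gain is never negative when pruning any taxon", {
  set.seed(73)
  backbone <- generate_true_tree(9, seed = 8)
  trees <- wandering_rogue_trees(backbone, c(3, 7, 12))
  base <- strict_consensus(trees)
  for (tax in trees[[1]]$tip.label) {
    pruned <- mrpsupertree:::prune_trees(trees, tax)
    restr <- ape::drop.tip(base, tax)
    gain <- mrpsupertree:::n_resolved_nodes(strict_consensus(pruned)) -
      mrpsupertree:::n_resolved_nodes(restr)
    expect_gte(gain, 0)
  }
})

test_that("the node-gain threshold separates strong from weak rogues", {
  # strong rogue: wanders across widely separated edges of a caterpillar,
  # collapsing the path between its attachment points
  cat_tree <- as_rooted(ape::read.tree(
    text = "(((((((((A,B),C),D),E),F),G),H),I),J);"))
  strong <- wandering_rogue_trees(cat_tree, c(3, 9, 16))
  wr_s <- identify_wildcards(strong, exclusion_threshold = 5)
  expect_length(wr_s$flagged, 1)
  expect_gte(wr_s$flagged[[1]]$node_gain, 5)
  expect_true(wr_s$flagged[[1]]$exclusion_recommended)

  # weak rogue: wanders between two nearby edges near the backbone root
  weak <- wandering_rogue_trees(cat_tree, c(17, 18))
  wr_w <- identify_wildcards(weak, exclusion_threshold = 5)
  expect_length(wr_w$flagged, 1)
  expect_lte(wr_w$flagged[[1]]$node_gain, 4)
  expect_false(wr_w$flagged[[1]]$exclusion_recommended)
})

test_that("pruned strict consensus handles the degenerate cases", {
  trees <- wandering_rogue_trees(generate_true_tree(8, seed = 3), c(2, 6))
  expect_equal(clade_keys(pruned_strict_consensus(trees, character(0))),
               clade_keys(strict_consensus(trees)))
  expect_error(pruned_strict_consensus(trees, trees[[1]]$tip.label[1:7]),
               "fewer than 3")
  # pruning an uninvolved stable leaf keeps the rest of the consensus
  stable <- setdiff(trees[[1]]$tip.label, "R")[1]
  pc <- pruned_strict_consensus(trees, stable)
  base <- strict_consensus(trees)
  keys_base <- clade_keys(ape::drop.tip(base, stable))
  expect_true(all(keys_base %in% clade_keys(pc)))
})
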