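rooted_trees <- function(...) {
  out <- lapply(list(...), function(s) as_rooted(ape::read.tree(text = s)))
  class(out) <- "multiPhylo"
  out
}

test_that("strict consensus keeps exactly the shared clades", {
  tr <- strict_consensus(rooted_trees("((A,B),(C,D));", "(((A,B),C),D);"))
  expect_equal(clade_keys(tr), "A,B")
  single <- rooted_trees("((A,B),(C,D));")
  expect_equal(clade_keys(strict_consensus(single)),
               clade_keys(single[[1]]))
  star <- strict_consensus(rooted_trees("((A,B),(C,D));", "((A,C),(B,D));"))
  expect_length(clade_keys(star), 0)
  expect_error(strict_consensus(rooted_trees("((A,B),C);", "((A,B),D);")),
               "leaf set")
})

test_that("semistrict consensus keeps uncontradicted clades", {
  tr <- semistrict_consensus(rooted_trees("((A,B),(C,D));", "((A,B),C,D);"))
  expect_setequal(clade_keys(tr), c("A,B", "C,D"))
  stars <- rooted_trees("(A,B,C,D);", "(A,B,C,D);")
  expect_length(clade_keys(semistrict_consensus(stars)), 0)
})

compute_brlen_collapse <- function(tr) {
  tr$edge.length <- rep(1, nrow(tr$edge))
  internal <- which(tr$edge[, 2] > length(tr$tip.label))
  if (length(internal) > 0)
    tr$edge.length[sample(internal, 1)] <- 0
  tr
}

test_that("strict is contained in semistrict on random inputs", {
  set.seed(47)
  for (i in 1:10) {
    trees <- lapply(1:4, function(j) {
      tr <- random_rooted_tree(7)
      # collapse a random internal edge sometimes to create polytomies
      if (runif(1) < 0.5) tr <- ape::di2multi(compute_brlen_collapse(tr))
      as_rooted(tr)
    })
    class(trees) <- "multiPhylo"
    st <- clade_keys(strict_consensus(trees))
    ss <- clade_keys(semistrict_consensus(trees))
    expect_true(all(st %in% ss))
    # every semistrict clade is compatible with every input clade
    for (k in ss) {
      s <- strsplit(k, ",")[[1]]
      for (tr in trees)
        for (cl in mrpsupertree:::clade_sets(tr))
          expect_true(mrpsupertree:::clades_compatible(s, cl))
    }
  }
})

test_that("frequency-difference consensus includes majority-backed clades only", {
  # clade AB in 3/4 trees, rival AC in 1/4: AB included
  trees <- rooted_trees("((A,B),(C,D));", "(((A,B),C),D);",
                        "(((A,B),D),C);", "((A,C),(B,D));")
  fd <- clade_keys(frequency_difference_consensus(trees))
  expect_true("A,B" %in% fd)
  expect_false("A,C" %in% fd)

  # two rivals tied 1:1 exclude each other
  tied <- rooted_trees("((A,B),(C,D));", "((A,C),(B,D));")
  expect_length(clade_keys(frequency_difference_consensus(tied)), 0)

  # identical inputs reduce to the strict consensus
  same <- rooted_trees("(((A,B),C),D);", "(((A,B),C),D);")
  expect_equal(clade_keys(frequency_difference_consensus(same)),
               clade_keys(strict_consensus(same)))
})

test_that("SPR distance: identity, one-move pairs, and the BFS oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  self <- spr_distance(t1, t1)
  expect_equal(self$d_spr, 0)
  expect_equal(self$similarity_pct, 100)
  expect_true(self$exact)

  set.seed(53)
  nbs <- spr_neighborhood(t1)
  for (t2 in nbs[sample(length(nbs), 5)]) {
    d <- spr_distance(t1, t2)
    expect_equal(d$d_spr, 1)
  }
})

test_that("the greedy bound never undercuts the exact distance (6 leaves)", {
  set.seed(59)
  for (i in 1:12) {
    t1 <- ape::rtree(6, br = NULL)
    t2 <- ape::rtree(6, br = NULL)
    t1$tip.label <- paste0("L", 1:6)
    t2$tip.label <- sample(paste0("L", 1:6))
    ex <- spr_distance(t1, t2)$d_spr
    bound <- mrpsupertree:::spr_prune_bound(ape::unroot(t1), ape::unroot(t2))
    expect_gte(bound, ex)
    if (ex <= 1) expect_equal(bound, ex)
  }
})

test_that("similarity decreases in the distance and symmetry holds", {
  set.seed(61)
  t1 <- ape::rtree(9, br = NULL)
  t1$tip.label <- paste0("L", 1:9)
  t2 <- ape::rtree(9, br = NULL)
  t2$tip.label <- sample(paste0("L", 1:9))
  d12 <- spr_distance(t1, t2)
  d21 <- spr_distance(t2, t1)
  expect_equal(d12$d_spr, d21$d_spr)
  expect_equal(d12$similarity_pct, 100 * (1 - d12$d_spr / (9 - 3)))
})

test_that("RF distance behaves as a metric on binary trees", {
  set.seed(67)
  ts <- lapply(1:3, function(i) {
    t <- ape::rtree(8, br = NULL)
    t$tip.label <- paste0("L", 1:8)
    ape::unroot(t)
  })
  expect_equal(phangorn::RF.dist(ts[[1]], ts[[1]]), 0)
  expect_equal(phangorn::RF.dist(ts[[1]], ts[[2]]),
               phangorn::RF.dist(ts[[2]], ts[[1]]))
  expect_lte(phangorn::RF.dist(ts[[1]], ts[[3]]),
             phangorn::RF.dist(ts[[1]], ts[[2]]) +
               phangorn::RF.dist(ts[[2]], ts[[3]]))
})

test_that("anticonsensus reports mutually contradicted clades only", {
  t1 <- as_rooted(ape::read.tree(text = "((A,B),(C,D));"))
  expect_length(anticonsensus(t1, t1), 0)

  t2 <- as_rooted(ape::read.tree(text = "((A,C),(B,D));"))
  a12 <- anticonsensus(t1, t2)
  expect_setequal(vapply(a12, paste, "", collapse = ","), c("A,B", "C,D"))
  a21 <- anticonsensus(t2, t1)
  expect_setequal(vapply(a21, paste, "", collapse = ","), c("A,C", "B,D"))

  star <- as_rooted(ape::read.tree(text = "(A,B,C,D);"))
  expect_length(anticonsensus(t1, star), 0)
})

test_that("character fit reproduces CI, RI and CI_min", {
  tr <- as_rooted(ape::read.tree(text = "(((A,B),(C,D)),(E,F));"))
  # character = exact clade {A,B}: one step, perfect fit
  m <- binary_matrix(rbind(A = "1", B = "1", C = "0", D = "0",
                           E = "0", F = "0"))
  fit <- character_fit(tr, m)$per_character
  expect_equal(fit$s, 1)
  expect_equal(fit$CI, 1)
  expect_equal(fit$RI, 1)

  # N = 5 presences: CI_min = 0.2
  m5 <- binary_matrix(rbind(A = "1", B = "1", C = "1", D = "1",
                            E = "1", F = "0"))
  expect_equal(character_fit(tr, m5)$per_character$CI_min, 0.2)

  # two steps, m = 1, g = 3: CI = 0.5, RI = 0.5 (verified by brute force)
  states <- c(A = "1", B = "1", C = "0", D = "0", E = "1", F = "0")
  expect_equal(brute_force_steps(tr, states), 2)
  m2 <- binary_matrix(matrix(states, ncol = 1,
                             dimnames = list(names(states), NULL)))
  fit2 <- character_fit(tr, m2)$per_character
  expect_equal(fit2$s, 2)
  expect_equal(fit2$CI, 0.5)
  expect_equal(fit2$RI, 0.5)
})

test_that("CI is at least CI_min and ensembles obey their bounds", {
  set.seed(71)
  tr <- random_rooted_tree(10)
  for (i in 1:30) {
    states <- sample(c("0", "1"), 10, replace = TRUE)
    if (length(unique(states)) < 2) next
    m <- binary_matrix(matrix(states, ncol = 1,
                              dimnames = list(tr$tip.label, NULL)))
    fit <- character_fit(tr, m)$per_character
    expect_gte(fit$CI, fit$CI_min - 1e-12)
  }
  m <- random_binary_matrix(10, 25)
  rownames(m$states) <- tr$tip.label
  m$taxa <- tr$tip.label
  fit <- character_fit(tr, m)
  expect_lte(fit$ensemble_CI, 1)
  per <- fit$per_character
  inf <- per$m > 0
  expect_gte(fit$ensemble_CI, sum(per$m[inf]) / sum(per$g[inf]))
})

test_that("tanglegram pairing tabulates both leaf orders", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  pair <- tanglegram_pairing(t1, t2)
  expect_equal(nrow(pair), 4)
  expect_equal(pair$taxon[pair$pos_t1 == 1],
               t1$tip.label[1])
  expect_equal(pair$pos_t2, match(pair$taxon, t2$tip.label))
})
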