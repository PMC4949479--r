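test_that("Fitch scoring matches direct cases and the brute-force oracle", {
  m <- binary_matrix(rbind(A = "1", B = "1", C = "0", D = "0"))
  expect_equal(fitch_score(ape::read.tree(text = "((A,B),(C,D));"), m), 1)
  expect_equal(fitch_score(ape::read.tree(text = "((A,C),(B,D));"), m), 2)
  expect_equal(brute_force_steps(ape::read.tree(text = "((A,C),(B,D));"),
                                 c(A = "1", B = "1", C = "0", D = "0")), 2)

  # a character that is missing in all but one taxon costs nothing
  m_q <- binary_matrix(rbind(A = c("1", "?"), B = c("0", "?"),
                             C = c("0", "?"), D = c("1", "1")))
  per <- fitch_score(ape::read.tree(text = "((A,B),(C,D));"), m_q,
                     per_character = TRUE)
  expect_equal(per[2], 0)
  # a character with no observed state at all violates the matrix invariant
  expect_error(binary_matrix(rbind(A = "?", B = "-", C = "?", D = "?")),
               "non-missing")

  expect_error(fitch_score(ape::read.tree(text = "((A,B),(C,E));"), m),
               "only in tree.*E")
})

test_that("Fitch score agrees with brute force on random trees and characters", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(5:7, 1)
    tr <- random_rooted_tree(n)
    states <- sample(c("0", "1", "?"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    names(states) <- tr$tip.label
    if (sum(states != "?") == 0) next
    m <- binary_matrix(matrix(states, ncol = 1,
                              dimnames = list(tr$tip.label, NULL)))
    expect_equal(fitch_score(tr, m), brute_force_steps(tr, states))
  }
})

test_that("fitch_score is invariant under rerooting", {
  set.seed(17)
  m <- random_binary_matrix(8, 12, p_missing = 0.15)
  tr <- random_rooted_tree(8, rownames(m$states))
  s0 <- fitch_score(tr, m)
  for (tip in tr$tip.label[1:4]) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_score(rr, m), s0)
  }
})

test_that("polytomies are scored as hard polytomies", {
  # star tree: steps = count of the rarer state
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  m <- binary_matrix(rbind(A = "1", B = "1", C = "0", D = "0", E = "0"))
  expect_equal(fitch_score(star, m), 2)
})

test_that("exhaustive search enumerates (2n-5)!! topologies and finds optima", {
  m4 <- code_tree(read_newick("((A,B),(C,D));"))
  res <- exhaustive_search(m4)
  expect_equal(res$n_topologies, 3)
  expect_equal(res$best_score, ncol(m4$states))
  expect_length(res$mp_trees, 1)
  expect_true("A,B" %in% split_keys(res$mp_trees[[1]]) ||
              "C,D" %in% split_keys(res$mp_trees[[1]]))

  # n=5: optimum equals the minimum over all 15 topologies scored by an
  # independent engine
  set.seed(23)
  for (i in 1:5) {
    m <- random_binary_matrix(5, 8)
    res <- exhaustive_search(m)
    expect_equal(res$n_topologies, 15)
    oracle <- min(vapply(all_unrooted_topologies(m$taxa),
                         function(t) phangorn_score(t, m), 1))
    expect_equal(res$best_score, oracle)
  }

  m11 <- random_binary_matrix(11, 5)
  expect_error(exhaustive_search(m11), "refus")
})

test_that("heuristic search never beats the exhaustive optimum and usually matches it", {
  set.seed(29)
  hits <- 0
  for (i in 1:10) {
    m <- random_binary_matrix(7, 12)
    ex <- exhaustive_search(m)
    he <- heuristic_search(m, search_config(n_addition_replicates = 5,
                                            seed = i))
    expect_gte(he$best_score, ex$best_score - 1e-9)
    hits <- hits + (abs(he$best_score - ex$best_score) < 1e-9)
    for (t in he$mp_trees)
      expect_equal(fitch_score(t, m), he$best_score)
  }
  expect_gte(hits, 9)
})

test_that("weight-0 characters and weight scaling behave as pure rescalings", {
  set.seed(31)
  m <- random_binary_matrix(7, 10)
  base <- exhaustive_search(m)

  extra <- binary_matrix(matrix(sample(c("0", "1"), 7, TRUE), ncol = 1,
                                dimnames = list(m$taxa, NULL)),
                         weights = 0)
  m0 <- merge_matrices(list(m, extra))
  with0 <- exhaustive_search(m0)
  expect_equal(with0$best_score, base$best_score)
  expect_setequal(vapply(with0$mp_trees, function(t)
    paste(split_keys(t), collapse = ";"), ""),
    vapply(base$mp_trees, function(t)
      paste(split_keys(t), collapse = ";"), ""))

  m5 <- binary_matrix(m$states, m$weights * 5, m$provenance)
  scaled <- exhaustive_search(m5)
  expect_equal(scaled$best_score, 5 * base$best_score)
  expect_length(scaled$mp_trees, length(base$mp_trees))
})

test_that("two compatible source trees combine into a displaying supertree", {
  t1 <- read_newick("(((A,B),C),E);")
  t2 <- read_newick("(((A,B),D),F);")
  srcs <- list(source_record("s1", "tree", "genomic_tree", t1, rooted = TRUE),
               source_record("s2", "tree", "genomic_tree", t2, rooted = TRUE))
  m <- apply_rooting(code_sources(srcs), srcs, "A")
  res <- heuristic_search(m, search_config(n_addition_replicates = 10,
                                           swap = "spr", seed = 3))
  expect_equal(res$best_score, 4)  # every character fits once
  rooted <- root_at_all0(res$mp_trees)
  # every MP supertree displays both sources: restricted clades contain each
  # source's clades
  for (st in rooted) {
    for (src in srcs) {
      restr <- ape::keep.tip(st, src$payload$tip.label)
      attr(restr, "rooted") <- TRUE
      expect_true(all(clade_keys(src$payload) %in% clade_keys(restr)))
    }
  }
})

test_that("ratchet iterations do not degrade the result", {
  set.seed(37)
  m <- random_binary_matrix(8, 14)
  plain <- heuristic_search(m, search_config(n_addition_replicates = 4,
                                             seed = 5))
  ratch <- heuristic_search(m, search_config(n_addition_replicates = 4,
                                             ratchet_iterations = 2,
                                             seed = 5))
  expect_lte(ratch$best_score, plain$best_score + 1e-9)
})

test_that("searches are deterministic given the seed", {
  set.seed(43)
  m <- random_binary_matrix(9, 10)
  a <- heuristic_search(m, search_config(n_addition_replicates = 3, seed = 77))
  b <- heuristic_search(m, search_config(n_addition_replicates = 3, seed = 77))
  expect_equal(a$best_score, b$best_score)
  expect_identical(lapply(a$mp_trees, ape::write.tree),
                   lapply(b$mp_trees, ape::write.tree))
})

test_that("character step bounds give the CI/RI ingredients", {
  expect_equal(char_step_bounds(c("1", "1", "0", "0", "0")), c(m = 1, g = 2))
  expect_equal(char_step_bounds(c("1", "0")), c(m = 1, g = 1))
  expect_equal(char_step_bounds(c("1", "1", "?", "?")), c(m = 0, g = 0))
})
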