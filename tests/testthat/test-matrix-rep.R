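test_that("tree coding follows the additive binary rule", {
  tr <- read_newick("((A,B),C);")
  m <- code_tree(tr, universe = c("A", "B", "C", "D"))
  expect_equal(ncol(m$states), 1)
  expect_equal(unname(m$states[, 1]), c("1", "1", "0", "-"))

  m2 <- code_tree(read_newick("(((A,B),C),D);"))
  got <- apply(m2$states, 2, function(col)
    paste(sort(rownames(m2$states)[col == "1"]), collapse = ","))
  expect_setequal(unname(got), c("A,B", "A,B,C"))

  # unrooted star has no nontrivial split
  star <- read_newick("(A,B,C);", rooted_hint = FALSE)
  expect_warning(m3 <- code_tree(ape::read.tree(text = "(A,B);")),
                 "fewer than 3")
  expect_equal(ncol(m3$states), 0)
  expect_equal(ncol(code_tree(star)$states), 0)
})

test_that("a rooted binary n-leaf tree yields exactly n-2 characters", {
  set.seed(7)
  for (n in c(5, 9, 16)) {
    tr <- random_rooted_tree(n)
    expect_equal(ncol(code_tree(tr)$states), n - 2)
  }
})

test_that("admixture coding applies the 10% threshold and borderline band", {
  q <- qmatrix(c("t1", "t2", "t3", "t4"),
               rbind(c(0.95, 0.05), c(0.90, 0.10),
                     c(0.12, 0.88), c(0.50, 0.50)))
  m <- code_admixture(q)
  expect_equal(unname(m$states[, 1]), c("1", "1", "1", "1"))
  expect_equal(unname(m$states[, 2]), c("0", "1", "1", "1"))

  mb <- code_admixture(q, admixture_config(0.10, c(0.05, 0.15)))
  expect_equal(unname(mb$states["t1", 2]), "?")
  expect_equal(unname(mb$states["t3", 1]), "?")

  # a cluster nobody reaches codes constant 0 and is uninformative
  q2 <- qmatrix(c("a", "b"), rbind(c(0.95, 0.05), c(0.97, 0.03)))
  m2 <- code_admixture(q2)
  expect_equal(unname(m2$states[, 2]), c("0", "0"))
  expect_false(any(is_informative(m2)))
})

test_that("merge unions taxa, fills inapplicable, and is order-independent", {
  m1 <- code_tree(read_newick("((A,B),C);"), source_id = "s1")
  m2 <- code_tree(read_newick("((B,C),D);"), source_id = "s2")
  mm <- merge_matrices(list(m1, m2))
  expect_setequal(mm$taxa, c("A", "B", "C", "D"))
  expect_equal(unname(mm$states["A", 2]), "-")
  expect_equal(unname(mm$states["D", 1]), "-")
  expect_equal(ncol(mm$states), ncol(m1$states) + ncol(m2$states))

  ab <- sort_columns(merge_matrices(list(m1, m2)))
  ba <- sort_columns(merge_matrices(list(m2, m1)))
  expect_equal(unname(ab$states[sort(ab$taxa), ]),
               unname(ba$states[sort(ba$taxa), ]))

  dbl <- merge_matrices(list(m1, m1))
  expect_equal(ncol(dbl$states), 2 * ncol(m1$states))
  expect_error(merge_matrices(list()), "empty")
})

test_that("merge never changes states", {
  set.seed(11)
  ms <- lapply(1:3, function(i) {
    tr <- random_rooted_tree(6, labels = sprintf("T%02d", sample(1:9, 6)))
    code_tree(tr, source_id = paste0("s", i))
  })
  mm <- merge_matrices(ms)
  off <- 0
  for (m in ms) {
    blk <- mm$states[m$taxa, off + seq_len(ncol(m$states)), drop = FALSE]
    expect_equal(unname(blk), unname(m$states))
    off <- off + ncol(m$states)
  }
})

test_that("rooting schemes score the all-0 outgroup per source treatment", {
  lang <- source_record("L1", "tree", "language_tree",
                        read_newick("((A,B),C);"), rooted = TRUE)
  mt <- source_record("M1", "tree", "mtdna_tree",
                      read_newick("((A,C),D);"), rooted = TRUE,
                      has_hominin_outgroup = FALSE)
  unr <- source_record("U1", "tree", "genomic_tree",
                       read_newick("((A,B),(C,D));", rooted_hint = FALSE),
                       rooted = FALSE)
  hom <- source_record("H1", "tree", "genomic_tree",
                       read_newick("((B,C),D);"), rooted = TRUE,
                       has_hominin_outgroup = TRUE)
  adm <- source_record("Q1", "admixture", "admixture_genomic",
                       qmatrix(c("A", "B"), rbind(c(0.9, 0.1), c(0.2, 0.8))))
  sources <- list(lang, mt, unr, hom, adm)
  merged <- code_sources(sources, universe = c("A", "B", "C", "D"))

  all0_for <- function(scheme, src_id) {
    m <- apply_rooting(merged, sources, scheme)
    unname(m$states["ALL0", m$provenance$source_id == src_id])
  }
  expect_true(all(all0_for("A", "L1") == "0"))   # rooted language tree
  expect_true(all(all0_for("A", "Q1") == "0"))   # plots rooted under A
  expect_true(all(all0_for("A", "U1") == "?"))   # unrooted tree never rooted
  expect_true(all(all0_for("B", "Q1") == "?"))   # only rooted source trees
  expect_true(all(all0_for("B", "L1") == "0"))
  expect_true(all(all0_for("C", "L1") == "?"))   # genetic/genomic trees only
  expect_true(all(all0_for("C", "M1") == "0"))
  expect_true(all(all0_for("D", "M1") == "?"))   # no hominin outgroup
  expect_true(all(all0_for("D", "H1") == "0"))
  expect_error(apply_rooting(merged, sources, "E"), "scheme")
})

test_that("weighting schemes reweight partitions without touching states", {
  trs <- list(
    source_record("G", "tree", "genomic_tree", read_newick("((A,B),C);"), TRUE),
    source_record("H", "tree", "hla_tree", read_newick("((A,C),D);"), TRUE),
    source_record("L", "tree", "language_tree", read_newick("((B,D),C);"), TRUE),
    source_record("Q", "admixture", "admixture_genomic",
                  qmatrix(c("A", "B"), rbind(c(0.9, 0.1), c(0.2, 0.8)))))
  m <- code_sources(trs, universe = c("A", "B", "C", "D"))
  part <- m$provenance$partition

  w1 <- apply_weights(m, 1)
  expect_true(all(w1$weights == 1))
  w2 <- apply_weights(m, 2)
  expect_true(all(w2$weights[part != "admixture_genomic"] == 1000))
  expect_true(all(w2$weights[part == "admixture_genomic"] == 1))
  w3 <- apply_weights(m, 3)
  expect_true(all(w3$weights[part %in% c("genomic_tree", "hla_tree")] == 1000))
  expect_true(all(w3$weights[part %in% c("language_tree", "admixture_genomic")] == 1))
  w4 <- apply_weights(m, 4)
  expect_true(all(w4$weights[part == "genomic_tree"] == 1000))
  expect_true(all(w4$weights[part == "hla_tree"] == 1))
  w3d <- apply_weights(m, 3, deactivate = TRUE)
  expect_true(all(w3d$weights[part %in% c("language_tree", "admixture_genomic")] == 0))

  for (w in list(w1, w2, w3, w4, w3d)) {
    expect_identical(w$states, m$states)
    expect_equal(ncol(w$states), ncol(m$states))
  }
  # total weight is a deterministic function of the partition census
  expect_equal(sum(w4$weights),
               1000 * sum(part == "genomic_tree") + sum(part != "genomic_tree"))
})

test_that("the MP tree implied by an admixture plot matches its clustering", {
  # K=2 plot perfectly splitting {A,B} vs {C,D}
  q <- qmatrix(c("A", "B", "C", "D"),
               rbind(c(0.98, 0.02), c(0.97, 0.03),
                     c(0.03, 0.97), c(0.02, 0.98)))
  tr <- implied_admixture_tree(q)
  expect_true("A,B" %in% split_keys(tr) || "C,D" %in% split_keys(tr))

  # nested K=2 and K=3 plots consistent with ((A,B),(C,(D,E)))
  crisp <- function(sets, taxa) {
    K <- length(sets)
    mem <- matrix(0.02 / (K - 1), length(taxa), K,
                  dimnames = list(taxa, NULL))
    for (k in seq_len(K)) mem[sets[[k]], k] <- 0.98
    qmatrix(taxa, mem / rowSums(mem))
  }
  taxa <- c("A", "B", "C", "D", "E")
  q2 <- crisp(list(c("A", "B"), c("C", "D", "E")), taxa)
  q3 <- crisp(list(c("A", "B"), "C", c("D", "E")), taxa)
  m <- merge_matrices(list(code_admixture(q2, source_id = "q2"),
                           code_admixture(q3, source_id = "q3")))
  res <- exhaustive_search(m)
  cons <- strict_consensus(res$mp_trees)
  sk <- split_keys(cons)  # splits keyed by the side without taxon A
  expect_true("A,B" %in% sk || "C,D,E" %in% sk)
  expect_true("D,E" %in% sk)

  # plot with a single informative cluster resolves exactly one clade
  q1 <- qmatrix(c("A", "B", "C", "D"),
                rbind(c(0.95, 0.05), c(0.93, 0.07),
                      c(0.05, 0.95), c(0.5, 0.5)))
  tr1 <- implied_admixture_tree(q1)
  expect_s3_class(tr1, "phylo")
})

test_that("MRP identity: search on a tree's own coding recovers the tree", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(8:15, 1)
    tt <- random_rooted_tree(n)
    src <- list(source_record("s", "tree", "genomic_tree", tt, rooted = TRUE))
    m <- apply_rooting(code_sources(src), src, "A")
    res <- heuristic_search(m, search_config(n_addition_replicates = 3,
                                             swap = "spr", seed = i))
    rooted <- root_at_all0(res$mp_trees)
    expect_length(rooted, 1)
    expect_equal(phangorn::RF.dist(rooted[[1]], tt), 0)
    expect_equal(res$best_score, n - 2)  # one step per coded clade
  }
})
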