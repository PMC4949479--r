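# Independent oracles used across the suite. These deliberately avoid the
# package's own scoring/search code paths.

# Brute-force Fitch: minimum changes of a binary character on a rooted tree
# by enumerating every ancestral state assignment. States: "0", "1", or
# missing ("?"/"-", free choice).
brute_force_steps <- function(tree, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nodes <- unique(tr$edge[, 1])
  k <- length(nodes)
  tip_state <- states[tr$tip.label]
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    assign_int <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    names(assign_int) <- nodes
    total <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tr$edge))) {
      p <- as.character(tr$edge[e, 1])
      ch <- tr$edge[e, 2]
      ps <- assign_int[[p]]
      if (ch <= n) {
        cs <- tip_state[ch]
        if (cs %in% c("?", "-")) next  # free: match parent at no cost
        total <- total + (as.integer(cs) != ps)
      } else {
        total <- total + (assign_int[[as.character(ch)]] != ps)
      }
      if (total >= best) { ok <- FALSE; break }
    }
    if (ok) best <- min(best, total)
  }
  best
}

# Weighted parsimony score through phangorn (independent engine).
phangorn_score <- function(tree, m) {
  states <- m$states
  states[states == "-"] <- "?"
  dat <- phangorn::phyDat(states, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  per_site <- phangorn::parsimony(tree, dat, site = "site")
  # phyDat compresses duplicate site patterns; map back through the index
  idx <- attr(dat, "index")
  sum(m$weights * per_site[idx])
}

# All unrooted binary topologies over the given labels, via phangorn.
all_unrooted_topologies <- function(labels) {
  phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
}

# Random binary matrix over n taxa (guaranteed >= 1 observed state/char).
random_binary_matrix <- function(n_taxa, n_char, p_missing = 0) {
  labs <- sprintf("T%02d", seq_len(n_taxa))
  repeat {
    s <- matrix(sample(c("0", "1"), n_taxa * n_char, replace = TRUE),
                n_taxa, n_char, dimnames = list(labs, NULL))
    if (p_missing > 0) {
      miss <- matrix(runif(n_taxa * n_char) < p_missing, n_taxa, n_char)
      s[miss] <- "?"
    }
    if (all(colSums(s == "0" | s == "1") >= 1)) break
  }
  binary_matrix(s)
}

# Random rooted binary tree with attribute rooted = TRUE.
random_rooted_tree <- function(n, labels = sprintf("T%02d", seq_len(n))) {
  tr <- ape::rtree(n, br = NULL)
  tr$tip.label <- sample(labels)
  tr <- ape::read.tree(text = ape::write.tree(tr))
  attr(tr, "rooted") <- TRUE
  tr
}

as_rooted <- function(tr) {
  attr(tr, "rooted") <- TRUE
  tr
}

clade_keys <- function(tree) {
  sort(vapply(mrpsupertree:::clade_sets(tree), function(s)
    paste(s, collapse = ","), ""))
}

split_keys <- function(tree) {
  sort(vapply(mrpsupertree:::split_sets(tree), function(s)
    paste(s, collapse = ","), ""))
}

# Build 3+ trees where rogue leaf R wanders across the given backbone edges.
wandering_rogue_trees <- function(backbone, edges) {
  out <- lapply(edges, function(e)
    as_rooted(mrpsupertree:::attach_leaf(backbone, "R", backbone$edge[e, 2])))
  class(out) <- "multiPhylo"
  out
}

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- mrpsupertree:::with_seed
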