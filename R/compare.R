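#' Subtree-prune-regraft (SPR) distance between two trees
#'
#' For leaf counts up to `exact_limit` the distance is exact, by
#' breadth-first search over the unrooted SPR graph. Above the limit a
#' greedy agreement-pruning upper bound is computed: prune units (single
#' leaves, or pendant subtrees shared by both trees with identical induced
#' topology) are removed one at a time, always the unit whose removal most
#' reduces the Robinson-Foulds distance of the restricted trees, until the
#' restrictions agree; each pruned unit can be regrafted with one SPR move,
#' so the count bounds the distance from above. Unresolved inputs are
#' resolved deterministically and flagged.
#'
#' The similarity percentage is `100 * (1 - d / (n - 3))`, where `n - 3` is
#' the number of inner edges of an unrooted binary tree (an upper bound on
#' the SPR distance), so identical trees score 100 and maximally distant
#' trees approach 0.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @param exact_limit largest leaf count for the exact BFS (default 8).
#' @return An object of class `tree_comparison`: list with `d_spr`, `exact`,
#'   `approximate`, `similarity_pct`, `rf`, `resolved_inputs` and
#'   `anticonsensus_clades` (both directions).
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
#' spr_distance(t1, t1)$similarity_pct
#' @export
spr_distance <- function(t1, t2, exact_limit = 8) {
  check_same_leaves(list(t1, t2))
  n <- length(t1$tip.label)
  if (n < 4) stop("need at least 4 leaves")
  resolved <- FALSE
  prep <- function(t) {
    u <- ape::unroot(t)
    if (!ape::is.binary(u)) {
      resolved <<- TRUE
      u <- ape::unroot(ape::multi2di(u, random = FALSE))
    }
    u
  }
  u1 <- prep(t1)
  u2 <- prep(t2)
  rf <- rf_quiet(u1, u2)
  if (rf == 0) {
    d <- 0
    exact <- TRUE
  } else if (n <= exact_limit) {
    d <- spr_bfs_between(u1, u2)
    exact <- TRUE
  } else {
    d <- spr_prune_bound(u1, u2)
    exact <- FALSE
  }
  structure(list(d_spr = d, exact = exact, approximate = !exact,
                 similarity_pct = 100 * (1 - d / (n - 3)),
                 rf = rf, resolved_inputs = resolved,
                 anticonsensus_clades = list(
                   t1_vs_t2 = anticonsensus(t1, t2),
                   t2_vs_t1 = anticonsensus(t2, t1))),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("SPR distance %d%s, similarity %.1f%%, RF %d\n",
              x$d_spr, if (x$exact) "" else " (upper bound)",
              x$similarity_pct, as.integer(x$rf)))
  invisible(x)
}

## Exact BFS distance between two unrooted binary phylo trees.
spr_bfs_between <- function(u1, u2) {
  taxa <- sort(u1$tip.label)
  to_edges <- function(u) {
    idx <- match(u$tip.label, taxa)  # common integer labelling across trees
    e <- u$edge
    e[e <= length(taxa)] <- idx[e[e <= length(taxa)]]
    e
  }
  d <- spr_bfs_cpp(to_edges(u1), to_edges(u2), length(taxa),
                   length(taxa))
  if (d < 0) stop("BFS failed to reach the target within the depth cap")
  d
}

## Greedy agreement-pruning upper bound. A prune unit is a single leaf or a
## pendant subtree that is a split of both trees with identical induced
## topology; regrafting one unit costs one SPR move, so the number of units
## pruned until the restrictions agree bounds the distance from above. At
## each step the unit whose removal most reduces the RF distance is pruned
## (ties: smaller unit, then label order).
rf_quiet <- function(a, b)
  as.numeric(suppressMessages(suppressWarnings(phangorn::RF.dist(a, b))))

spr_prune_bound <- function(u1, u2) {
  pruned <- 0L
  repeat {
    if (length(u1$tip.label) <= 3) return(pruned)
    if (rf_quiet(u1, u2) == 0) return(pruned)
    units <- prune_units(u1, u2)
    best <- Inf
    best_unit <- NULL
    for (un in units) {
      if (length(u1$tip.label) - length(un) < 4) next
      r <- rf_quiet(ape::drop.tip(u1, un), ape::drop.tip(u2, un))
      if (r < best) {
        best <- r
        best_unit <- un
      }
    }
    if (is.null(best_unit)) return(pruned + 1L)  # collapse to agreement
    u1 <- ape::drop.tip(u1, best_unit)
    u2 <- ape::drop.tip(u2, best_unit)
    pruned <- pruned + 1L
    if (best == 0) return(pruned)
  }
}

prune_units <- function(u1, u2) {
  leaves <- sort(u1$tip.label)
  units <- lapply(leaves, function(x) x)
  s1 <- split_sets(u1)
  k2 <- vapply(split_sets(u2), set_key, "")
  shared <- s1[vapply(s1, set_key, "") %in% k2]
  ## identical induced pendant structure: compare the restrictions to the
  ## unit plus one fixed outside leaf (which marks the attachment point)
  shared <- shared[vapply(shared, function(s) {
    if (length(s) > length(leaves) - 4L) return(FALSE)
    if (length(s) == 2L) return(TRUE)
    o <- setdiff(leaves, s)[1]
    rf_quiet(ape::keep.tip(u1, c(s, o)), ape::keep.tip(u2, c(s, o))) == 0
  }, TRUE)]
  ord <- order(vapply(shared, length, 1L), vapply(shared, set_key, ""))
  c(units, shared[ord])
}

#' SPR neighborhood of a tree
#'
#' All distinct unrooted topologies one SPR move away; mainly a building
#' block for tests and for constructing distance-1 pairs.
#'
#' @param tree a binary `phylo`.
#' @return A `multiPhylo`.
#' @export
spr_neighborhood <- function(tree) {
  u <- ape::unroot(tree)
  taxa <- sort(u$tip.label)
  e <- u$edge
  e[e <= length(taxa)] <- match(u$tip.label, taxa)[e[e <= length(taxa)]]
  strs <- spr_neighbors_cpp(e, length(taxa))
  engine_trees_to_phylo(strs, taxa)
}

#' Anticonsensus: clades of one tree contradicted by another
#'
#' The clades of `t1` that are absent from `t2` and incompatible with at
#' least one clade of `t2` (clades merely missing from an unresolved `t2`
#' are not contradicted).
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return List of taxon-label vectors (possibly empty).
#' @export
anticonsensus <- function(t1, t2) {
  check_same_leaves(list(t1, t2))
  rooted <- (isTRUE(attr(t1, "rooted")) || ape::is.rooted(t1)) &&
    (isTRUE(attr(t2, "rooted")) || ape::is.rooted(t2))
  leaves <- sort(t1$tip.label)
  if (rooted) {
    c1 <- clade_sets(t1)
    c2 <- clade_sets(t2)
    compat <- clades_compatible
  } else {
    c1 <- split_sets(t1)
    c2 <- split_sets(t2)
    compat <- function(a, b) splits_compatible(a, b, leaves)
  }
  k2 <- vapply(c2, set_key, "")
  out <- list()
  for (s in c1) {
    if (set_key(s) %in% k2) next
    if (any(!vapply(c2, function(x) compat(s, x), TRUE)))
      out <- c(out, list(s))
  }
  out
}

#' Character fit on a reference tree: consistency and retention indices
#'
#' For each binary character: `s` = observed minimal steps on the tree
#' (Fitch), `m` = minimum conceivable steps, `g` = maximum conceivable steps
#' (star tree), `CI = m/s`, `RI = (g - s)/(g - m)`, `N` = taxa scored 1 and
#' `CI_min = 1/N`, the lowest CI a binary character with `N` presences can
#' attain on any tree, making fit comparable across groups of different
#' size. Ensemble values are `CI = sum(m)/sum(s)` and
#' `RI = (sum(g) - sum(s))/(sum(g) - sum(m))` over informative characters.
#'
#' @param tree a `phylo` covering the matrix taxa (tips absent from the
#'   matrix are treated as inapplicable).
#' @param m a [binary_matrix()].
#' @return An object of class `character_fit`: list with `per_character`
#'   data frame and `ensemble_CI`, `ensemble_RI`.
#' @export
character_fit <- function(tree, m) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "binary_matrix"))
  if (!all(m$taxa %in% tree$tip.label))
    stop("tree does not cover matrix taxa: ",
         paste(setdiff(m$taxa, tree$tip.label), collapse = ", "))
  full <- matrix("-", nrow = length(tree$tip.label), ncol = ncol(m$states),
                 dimnames = list(tree$tip.label, colnames(m$states)))
  full[m$taxa, ] <- m$states
  mf <- binary_matrix(full, m$weights, m$provenance)
  s <- fitch_score(tree, mf, per_character = TRUE)
  bounds <- t(apply(mf$states, 2, char_step_bounds))
  N <- colSums(mf$states == "1")
  mm <- bounds[, "m"]
  g <- bounds[, "g"]
  CI <- ifelse(mm > 0, mm / s, NA_real_)
  RI <- ifelse(g > mm, (g - s) / (g - mm), NA_real_)
  CI_min <- ifelse(N > 0, 1 / N, NA_real_)
  per <- data.frame(character = colnames(mf$states), s = as.numeric(s),
                    m = as.numeric(mm), g = as.numeric(g),
                    N = as.numeric(N), CI = CI, RI = RI, CI_min = CI_min,
                    stringsAsFactors = FALSE)
  use <- mm > 0  # informative (variable) characters enter the ensembles
  ens_CI <- if (any(use)) sum(mm[use]) / sum(s[use]) else NA_real_
  ens_RI <- if (any(use) && sum(g[use]) > sum(mm[use]))
    (sum(g[use]) - sum(s[use])) / (sum(g[use]) - sum(mm[use])) else NA_real_
  structure(list(per_character = per, ensemble_CI = ens_CI,
                 ensemble_RI = ens_RI),
            class = "character_fit")
}

#' @export
print.character_fit <- function(x, ...) {
  cat(sprintf("Character fit: %d characters, ensemble CI %.3f, RI %.3f\n",
              nrow(x$per_character), x$ensemble_CI, x$ensemble_RI))
  invisible(x)
}

#' Tanglegram leaf pairing table
#'
#' Ordered leaf pairing between two trees (the data a tanglegram plot would
#' connect); no graphics are produced.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return Data frame with the position of every leaf in each tree's
#'   plotting order.
#' @export
tanglegram_pairing <- function(t1, t2) {
  check_same_leaves(list(t1, t2))
  o1 <- t1$tip.label
  o2 <- t2$tip.label
  data.frame(taxon = o1, pos_t1 = seq_along(o1),
             pos_t2 = match(o1, o2), stringsAsFactors = FALSE)
}
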