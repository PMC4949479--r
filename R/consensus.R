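## Consensus methods operate on clade sets. Rooted inputs use rooted clade
## semantics directly. Unrooted inputs are mapped to a common rooted
## representation (rooted at the alphabetically first leaf), under which
## clades correspond one-to-one to splits; the consensus is then returned in
## that representation with attribute rooted = FALSE.

consensus_prepare <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(length(trees) >= 1)
  leaves <- check_same_leaves(trees)
  rooted <- all(vapply(trees, function(t) isTRUE(attr(t, "rooted")) ||
                         ape::is.rooted(t), TRUE))
  cl <- if (rooted) lapply(trees, clade_sets) else lapply(trees, split_sets)
  list(trees = trees, leaves = leaves, rooted = rooted, clades = cl)
}

consensus_finish <- function(leaves, clades, rooted) {
  out <- build_tree_from_clades(leaves, clades)
  attr(out, "rooted") <- rooted
  out
}

#' Strict consensus tree
#'
#' Keeps exactly the clades (splits, for unrooted inputs) present in every
#' input tree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) over one leaf set.
#' @return A `phylo`.
#' @examples
#' trees <- c(ape::read.tree(text = "((A,B),(C,D));"),
#'            ape::read.tree(text = "(((A,B),C),D);"))
#' ape::write.tree(strict_consensus(trees))
#' @export
strict_consensus <- function(trees) {
  p <- consensus_prepare(trees)
  keys <- lapply(p$clades, function(cl) vapply(cl, set_key, ""))
  shared <- Reduce(intersect, keys)
  consensus_finish(p$leaves, lapply(shared, key_to_set), p$rooted)
}

#' Semistrict (combinable components) consensus tree
#'
#' Keeps the clades present in at least one input and contradicted by none,
#' assembled greedily into a mutually compatible set by frequency, then
#' size, then label order (deterministic).
#'
#' @inheritParams strict_consensus
#' @return A `phylo`.
#' @export
semistrict_consensus <- function(trees) {
  p <- consensus_prepare(trees)
  sel <- combinable_components(p)
  consensus_finish(p$leaves, sel, p$rooted)
}

combinable_components <- function(p) {
  keys <- lapply(p$clades, function(cl) vapply(cl, set_key, ""))
  if (length(unlist(keys)) == 0) return(list())
  tab <- table(unlist(keys))
  cand <- names(tab)
  compat_fun <- if (p$rooted) clades_compatible else
    function(a, b) splits_compatible(a, b, p$leaves)
  uncontradicted <- vapply(cand, function(k) {
    s <- key_to_set(k)
    for (cl in p$clades)
      for (x in cl) if (!compat_fun(s, x)) return(FALSE)
    TRUE
  }, TRUE)
  cand <- cand[uncontradicted]
  freq <- as.integer(tab[cand])
  size <- vapply(cand, function(k) length(key_to_set(k)), 1L)
  ord <- order(-freq, -size, cand)
  greedy_compatible(lapply(cand[ord], key_to_set), compat_fun)
}

greedy_compatible <- function(sets, compat_fun) {
  sel <- list()
  for (s in sets) {
    ok <- all(vapply(sel, function(x) compat_fun(s, x), TRUE))
    if (ok) sel <- c(sel, list(s))
  }
  sel
}

#' Frequency-difference consensus tree
#'
#' Includes a clade iff its frequency across the input trees strictly
#' exceeds the frequency of every clade incompatible with it (ties exclude
#' both rivals); the resulting set is made mutually compatible greedily in
#' descending frequency.
#'
#' @inheritParams strict_consensus
#' @return A `phylo`.
#' @export
frequency_difference_consensus <- function(trees) {
  p <- consensus_prepare(trees)
  keys <- lapply(p$clades, function(cl) vapply(cl, set_key, ""))
  if (length(unlist(keys)) == 0)
    return(consensus_finish(p$leaves, list(), p$rooted))
  tab <- table(unlist(keys))
  cand <- names(tab)
  sets <- lapply(cand, key_to_set)
  freq <- as.integer(tab)
  compat_fun <- if (p$rooted) clades_compatible else
    function(a, b) splits_compatible(a, b, p$leaves)
  keep <- vapply(seq_along(sets), function(i) {
    rivals <- freq[vapply(seq_along(sets), function(j)
      j != i && !compat_fun(sets[[i]], sets[[j]]), TRUE)]
    length(rivals) == 0 || freq[i] > max(rivals)
  }, TRUE)
  ord <- order(-freq[keep], cand[keep])
  consensus_finish(p$leaves,
                   greedy_compatible(lapply(which(keep)[ord], function(i)
                     sets[[i]]), compat_fun),
                   p$rooted)
}
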