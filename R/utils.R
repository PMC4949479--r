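## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards, so generators are deterministic without clobbering
#' the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a base seed and a stream index, kept within the
## 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647L)
}

## Canonical key for a set of taxon labels.
set_key <- function(x) paste(sort(x), collapse = "\r")
key_to_set <- function(k) strsplit(k, "\r", fixed = TRUE)[[1]]

## Rooted-clade compatibility: two taxon sets are compatible iff nested or
## disjoint (within a common leaf universe).
clades_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

## Unrooted split compatibility over a common leaf set: A|A' vs B|B' are
## compatible iff at least one of the four pairwise intersections is empty.
splits_compatible <- function(a, b, leaves) {
  ac <- setdiff(leaves, a)
  bc <- setdiff(leaves, b)
  length(intersect(a, b)) == 0L || length(intersect(a, bc)) == 0L ||
    length(intersect(ac, b)) == 0L || length(intersect(ac, bc)) == 0L
}

## Nontrivial clades (taxon-label sets) of a rooted tree: all internal nodes
## except the root, sizes 2..(n-1).
clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3) return(list())
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- lapply(pp, function(i) sort(labs[i]))
  out <- out[vapply(out, length, 1L) < n & vapply(out, length, 1L) >= 2L]
  unique(out)
}

## Nontrivial splits of a tree treated as unrooted, represented as the side
## not containing the reference leaf (the alphabetically first label).
split_sets <- function(tree) {
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  n <- length(labs)
  cl <- clade_sets(tree)
  out <- lapply(cl, function(s) if (ref %in% s) sort(setdiff(labs, s)) else s)
  out <- out[vapply(out, length, 1L) >= 2L & vapply(out, length, 1L) <= n - 2L]
  unique(out)
}

## Build a rooted phylo from a set of mutually compatible nontrivial clades.
build_tree_from_clades <- function(leaves, clades) {
  leaves <- sort(leaves)
  clades <- unique(lapply(clades, sort))
  if (length(clades) >= 2) {
    for (i in seq_len(length(clades) - 1L))
      for (j in (i + 1L):length(clades))
        if (!clades_compatible(clades[[i]], clades[[j]]))
          stop("clades are not mutually compatible")
  }
  assemble <- function(set, cl) {
    cl <- cl[vapply(cl, function(x) length(x) < length(set), TRUE)]
    if (length(cl) == 0) {
      if (length(set) == 1) return(set)
      return(paste0("(", paste(set, collapse = ","), ")"))
    }
    sizes <- vapply(cl, length, 1L)
    ord <- order(-sizes)
    maximal <- list()
    covered <- character(0)
    for (k in ord) {
      s <- cl[[k]]
      if (!length(intersect(s, covered))) {
        maximal <- c(maximal, list(s))
        covered <- c(covered, s)
      }
    }
    parts <- character(0)
    for (s in maximal) {
      inner <- cl[vapply(cl, function(x) all(x %in% s) && length(x) < length(s), TRUE)]
      parts <- c(parts, assemble(s, inner))
    }
    singles <- setdiff(set, covered)
    parts <- c(parts, singles)
    if (length(parts) == 1) return(parts)
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  txt <- assemble(leaves, clades)
  if (!startsWith(txt, "(")) txt <- paste0("(", txt, ")")
  ape::read.tree(text = paste0(txt, ";"))
}

## Count of resolved (nontrivial, non-root) nodes of a tree.
n_resolved_nodes <- function(tree) length(clade_sets(tree))

## Check that trees share one leaf set; error otherwise.
check_same_leaves <- function(trees) {
  ref <- sort(trees[[1]]$tip.label)
  for (t in trees[-1])
    if (!identical(sort(t$tip.label), ref))
      stop("trees do not share an identical leaf set")
  invisible(ref)
}
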