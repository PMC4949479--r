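#' Maximum-parsimony search configuration
#'
#' Desk-scale defaults; published analyses of this kind use many more
#' addition replicates (the study-scale value is 10,000), which is a plain
#' parameter here.
#'
#' @param n_addition_replicates random addition sequence replicates
#'   (default 100).
#' @param swap branch-swapping move set: `"nni"`, `"spr"` or `"tbr"`
#'   (default `"tbr"`).
#' @param ratchet_iterations parsimony-ratchet rounds per replicate
#'   (default 0 = off).
#' @param seed integer RNG seed; searches are deterministic given the seed.
#' @param max_trees_retained cap on the number of equally parsimonious trees
#'   kept (default 1000); exceeding it flags the result truncated.
#' @param exhaustive_limit largest taxon count accepted by
#'   [exhaustive_search()] (default 9, hard cap 10).
#' @return An object of class `search_config`.
#' @export
search_config <- function(n_addition_replicates = 100,
                          swap = c("tbr", "spr", "nni"),
                          ratchet_iterations = 0,
                          seed = 1L,
                          max_trees_retained = 1000,
                          exhaustive_limit = 9) {
  swap <- match.arg(swap)
  stopifnot(n_addition_replicates >= 1, ratchet_iterations >= 0,
            max_trees_retained >= 1, exhaustive_limit <= 10)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 swap = swap,
                 ratchet_iterations = as.integer(ratchet_iterations),
                 seed = as.integer(seed),
                 max_trees_retained = as.integer(max_trees_retained),
                 exhaustive_limit = as.integer(exhaustive_limit)),
            class = "search_config")
}

## Translate engine canonical Newick (labels t0..t{n-1}) into phylo objects
## labelled with the matrix taxa. Trees are unrooted topologies.
engine_trees_to_phylo <- function(strings, taxa) {
  trees <- lapply(strings, function(s) {
    tr <- ape::read.tree(text = s)
    idx <- as.integer(sub("^t", "", tr$tip.label)) + 1L
    tr$tip.label <- taxa[idx]
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

## Drop weight-0 (deactivated) characters before scoring; they cannot affect
## the optimum. Keeps at least one column to avoid degenerate engine input.
drop_deactivated <- function(m) {
  keep <- m$weights > 0
  if (all(keep)) return(m)
  if (!any(keep)) stop("all characters are deactivated (weight 0)")
  binary_matrix(m$states[, keep, drop = FALSE], m$weights[keep],
                m$provenance[keep, , drop = FALSE])
}

#' Weighted Fitch parsimony score of a tree
#'
#' Sum over characters of weight times the minimal number of state changes.
#' Polytomies are treated as hard; `?` and `-` are both fully missing
#' (any-state) during optimization. The score is a property of the unrooted
#' topology (invariant under rerooting).
#'
#' @param tree a `phylo` whose tips equal the matrix taxa.
#' @param m a [binary_matrix()].
#' @param per_character return the unweighted per-character step counts
#'   instead of the weighted total.
#' @return Numeric scalar (or vector when `per_character = TRUE`).
#' @examples
#' s <- rbind(A = "1", B = "1", C = "0", D = "0")
#' fitch_score(ape::read.tree(text = "((A,B),(C,D));"), binary_matrix(s))
#' @export
fitch_score <- function(tree, m, per_character = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "binary_matrix"))
  if (!setequal(tree$tip.label, m$taxa)) {
    only_tree <- setdiff(tree$tip.label, m$taxa)
    only_mat <- setdiff(m$taxa, tree$tip.label)
    stop("taxon mismatch between tree and matrix; only in tree: {",
         paste(only_tree, collapse = ", "), "}; only in matrix: {",
         paste(only_mat, collapse = ", "), "}")
  }
  if (ncol(m$states) == 0)
    return(if (per_character) numeric(0) else 0)
  tr <- ape::reorder.phylo(tree, "postorder")
  codes <- state_codes(m, taxa = tr$tip.label)
  steps <- sankoff_steps_cpp(tr$edge, length(tr$tip.label), codes)
  steps[is.na(steps)] <- 0  # all-missing characters cost nothing
  if (per_character) steps else sum(m$weights * steps)
}

#' Exhaustive maximum-parsimony search (oracle)
#'
#' Enumerates all distinct unrooted binary topologies ((2n-5)!! for n
#' leaves), scores each, and returns the complete set of most parsimonious
#' trees. Refuses taxon counts above `exhaustive_limit`.
#'
#' @param m a [binary_matrix()].
#' @param exhaustive_limit cap on the taxon count (default 9).
#' @return A `search_result`: list with `best_score`, `mp_trees`
#'   (`multiPhylo`, unrooted), `evaluations`, `n_topologies`,
#'   `exhausted = TRUE`.
#' @export
exhaustive_search <- function(m, exhaustive_limit = 9) {
  stopifnot(inherits(m, "binary_matrix"))
  n <- length(m$taxa)
  if (n > exhaustive_limit)
    stop(sprintf("refusing exhaustive search on %d taxa (limit %d)",
                 n, exhaustive_limit))
  if (n < 4) stop("need at least 4 taxa")
  m2 <- drop_deactivated(m)
  res <- exhaustive_search_cpp(state_codes(m2), m2$weights)
  structure(list(best_score = res$best_score,
                 mp_trees = engine_trees_to_phylo(res$trees, m2$taxa),
                 evaluations = res$evaluations,
                 n_topologies = res$n_topologies,
                 exhausted = TRUE, truncated = FALSE),
            class = "search_result")
}

#' Heuristic maximum-parsimony search
#'
#' For each replicate: random taxon addition order, greedy stepwise
#' addition (ties broken by a seeded uniform choice), then hill-climbing
#' branch swapping with the configured move set to a local optimum;
#' optionally a parsimony ratchet (reweight-perturb-and-swap rounds). The
#' distinct best trees pooled across replicates are expanded with
#' equal-score neighbors so the returned MP set reflects alternative equally
#' parsimonious arrangements, up to `max_trees_retained` (exceeding the cap
#' flags the result truncated, not an error). Deterministic given the seed.
#'
#' @param m a [binary_matrix()] with at least 4 taxa.
#' @param cfg a [search_config()].
#' @return A `search_result` (see [exhaustive_search()]) with
#'   `exhausted = FALSE`.
#' @export
heuristic_search <- function(m, cfg = search_config()) {
  stopifnot(inherits(m, "binary_matrix"), inherits(cfg, "search_config"))
  if (length(m$taxa) < 4) stop("need at least 4 taxa")
  m2 <- drop_deactivated(m)
  swap_code <- match(cfg$swap, c("nni", "spr", "tbr")) - 1L
  res <- heuristic_search_cpp(state_codes(m2), m2$weights,
                              cfg$n_addition_replicates, swap_code,
                              cfg$ratchet_iterations, cfg$seed,
                              cfg$max_trees_retained)
  structure(list(best_score = res$best_score,
                 mp_trees = engine_trees_to_phylo(res$trees, m2$taxa),
                 evaluations = res$evaluations,
                 n_topologies = NA_real_,
                 exhausted = FALSE, truncated = res$truncated),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("MP search result: best score %s, %d tree(s)%s%s\n",
              format(x$best_score), length(x$mp_trees),
              if (x$exhausted) " [exhaustive]" else "",
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Minimum and maximum conceivable steps of a binary character
#'
#' The ingredients of the consistency and retention indices: `m` (minimum
#' steps on any tree; 1 for an informative binary character) and `g`
#' (maximum steps, attained on the star tree; the count of the rarer
#' observed state). Missing entries are excluded; characters constant among
#' observed states give `(0, 0)`.
#'
#' @param states character vector over `"0" "1" "?" "-"`.
#' @return Named numeric vector `c(m = , g = )`.
#' @examples
#' char_step_bounds(c("1", "1", "0", "0", "0"))
#' @export
char_step_bounds <- function(states) {
  n1 <- sum(states == "1")
  n0 <- sum(states == "0")
  if (n1 == 0 || n0 == 0) return(c(m = 0, g = 0))
  c(m = 1, g = min(n0, n1))
}

#' Root MP trees at the all-0 outgroup and drop it
#'
#' Search operates on unrooted topologies; when the matrix contains the
#' hypothetical `ALL0` outgroup, rooting each MP tree on it and removing it
#' yields the rooted supertree(s) over the real taxa.
#'
#' @param trees a `multiPhylo` (or single `phylo`) containing tip `ALL0`.
#' @return A `multiPhylo` of rooted trees without `ALL0`.
#' @export
root_at_all0 <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  out <- lapply(trees, function(tr) {
    if (!ALL0 %in% tr$tip.label) stop("tree has no ALL0 outgroup tip")
    r <- ape::root(tr, outgroup = ALL0, resolve.root = TRUE)
    r <- ape::drop.tip(r, ALL0)
    attr(r, "rooted") <- TRUE
    r
  })
  class(out) <- "multiPhylo"
  out
}
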