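#' The 4 x 4 sensitivity parameter grid
#'
#' Cartesian product of the four weighting schemes (1-4) and four rooting
#' schemes (A-D), labelled `"1.A"` through `"4.D"` in deterministic order.
#'
#' @return Data frame with columns `weighting`, `rooting`, `label` (16 rows).
#' @examples
#' build_parameter_grid()$label
#' @export
build_parameter_grid <- function() {
  g <- expand.grid(rooting = c("A", "B", "C", "D"), weighting = 1:4,
                   stringsAsFactors = FALSE)[, c("weighting", "rooting")]
  g$label <- paste0(g$weighting, ".", g$rooting)
  rownames(g) <- g$label
  g
}

#' Run the weighting-by-rooting sensitivity analysis
#'
#' For each cell of the grid: code sources, merge, apply the cell's rooting
#' treatment (all-0 outgroup) and partition weights, run the MP search, root
#' the MP trees at the outgroup, and summarize them as strict and semistrict
#' consensus trees. Deterministic given `search_cfg$seed` (each cell draws a
#' derived seed).
#'
#' @param sources list of [source_record()]s.
#' @param grid a parameter grid as from [build_parameter_grid()] (subset
#'   rows to run fewer cells).
#' @param search_cfg a [search_config()].
#' @param universe optional taxon universe.
#' @param admix_cfg an [admixture_config()].
#' @param factor upweighting factor (default 1000).
#' @param deactivate logical; weight the low class 0 instead of 1.
#' @return An object of class `sensitivity_result`: named list of cells,
#'   each with `label`, `search` (a `search_result` whose `mp_trees` are
#'   rooted, outgroup dropped), `strict`, `semistrict`.
#' @export
run_sensitivity <- function(sources, grid = build_parameter_grid(),
                            search_cfg = search_config(),
                            universe = NULL,
                            admix_cfg = admixture_config(),
                            factor = 1000, deactivate = FALSE) {
  stopifnot(nrow(grid) >= 1)
  merged <- code_sources(sources, universe, admix_cfg)
  cells <- vector("list", nrow(grid))
  names(cells) <- grid$label
  for (i in seq_len(nrow(grid))) {
    label <- grid$label[i]
    res <- tryCatch({
      m <- apply_rooting(merged, sources, grid$rooting[i])
      m <- apply_weights(m, grid$weighting[i], factor = factor,
                         deactivate = deactivate)
      cfg <- search_cfg
      cfg$seed <- derive_seed(search_cfg$seed, i)
      sr <- heuristic_search(m, cfg)
      sr$mp_trees <- root_at_all0(sr$mp_trees)
      sr
    }, error = function(e)
      stop(sprintf("sensitivity cell %s failed: %s", label,
                   conditionMessage(e)), call. = FALSE))
    cells[[i]] <- list(label = label, search = res,
                       strict = strict_consensus(res$mp_trees),
                       semistrict = semistrict_consensus(res$mp_trees))
  }
  structure(cells, class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d parameter set(s)\n", length(x)))
  for (cell in x)
    cat(sprintf("  %-4s score %-10s %d MP tree(s), %d strict consensus node(s)\n",
                cell$label, format(cell$search$best_score),
                length(cell$search$mp_trees),
                n_resolved_nodes(cell$strict)))
  invisible(x)
}

## Candidate wildcard units: single taxa plus cherries (2-taxon clades)
## appearing in at least one tree.
wildcard_candidates <- function(trees, taxa) {
  cands <- lapply(taxa, function(t) t)
  cherries <- unique(unlist(lapply(trees, function(tr) {
    cl <- clade_sets(tr)
    vapply(cl[vapply(cl, length, 1L) == 2L], set_key, "")
  })))
  c(cands, lapply(cherries, key_to_set))
}

#' Identify wildcard (rogue) taxa from a set of MP trees
#'
#' Iterative prune-and-measure procedure: for every candidate (each taxon,
#' plus every cherry occurring in a tree) compute how many resolved nodes
#' the strict consensus gains when the candidate is pruned from every tree;
#' greedily prune the maximum-gain candidate (ties broken by label order)
#' while the gain is at least `min_gain`. Reports, per pruned candidate, the
#' node gain at its removal step, the alternative attachment positions it
#' occupied across the input trees (sister groups on the remaining leaves),
#' and whether exclusion is recommended (`node_gain >= exclusion_threshold`).
#'
#' @param trees `multiPhylo` of at least 2 trees over one leaf set.
#' @param min_gain smallest node gain that keeps the greedy pruning going
#'   (default 1).
#' @param exclusion_threshold node gain at or above which exclusion from the
#'   dataset is recommended (default 5).
#' @return An object of class `wildcard_report`: list with `flagged` (list
#'   of per-candidate records), `pruned_taxa`, `consensus`
#'   (pruned strict consensus), `baseline_nodes`, `final_nodes`.
#' @export
identify_wildcards <- function(trees, min_gain = 1, exclusion_threshold = 5) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(length(trees) >= 2)
  taxa <- check_same_leaves(trees)
  cur <- trees
  flagged <- list()
  pruned <- character(0)
  strict_cur <- strict_consensus(cur)
  baseline <- n_resolved_nodes(strict_cur)
  repeat {
    remaining <- sort(cur[[1]]$tip.label)
    if (length(remaining) < 4) break
    cands <- wildcard_candidates(cur, remaining)
    cands <- cands[vapply(cands, function(s)
      all(s %in% remaining) && length(remaining) - length(s) >= 3, TRUE)]
    if (length(cands) == 0) break
    keys <- vapply(cands, set_key, "")
    cands <- cands[order(keys)]
    ## gain = resolution of the consensus of the pruned trees, relative to
    ## the current consensus restricted to the same reduced leaf set; this
    ## is always >= 0 (restricting a clade shared by all trees keeps it
    ## shared after pruning)
    gains <- vapply(cands, function(s) {
      pr <- prune_trees(cur, s)
      restr <- ape::drop.tip(strict_cur, s)
      attr(restr, "rooted") <- isTRUE(attr(strict_cur, "rooted"))
      n_resolved_nodes(strict_consensus(pr)) - n_resolved_nodes(restr)
    }, 1)
    best <- which.max(gains)  # first max = lexicographically smallest
    if (gains[best] < min_gain) break
    cand <- cands[[best]]
    flagged <- c(flagged, list(list(
      taxa = cand,
      node_gain = as.integer(gains[best]),
      alternative_positions = attachment_positions(cur, cand),
      exclusion_recommended = gains[best] >= exclusion_threshold)))
    pruned <- c(pruned, cand)
    cur <- prune_trees(cur, cand)
    strict_cur <- strict_consensus(cur)
  }
  structure(list(flagged = flagged, pruned_taxa = pruned,
                 consensus = strict_cur,
                 baseline_nodes = baseline,
                 final_nodes = n_resolved_nodes(strict_cur)),
            class = "wildcard_report")
}

#' @export
print.wildcard_report <- function(x, ...) {
  cat(sprintf("Wildcard report: %d unstable unit(s), consensus %d -> %d nodes\n",
              length(x$flagged), x$baseline_nodes, x$final_nodes))
  for (f in x$flagged)
    cat(sprintf("  {%s}: gain %d, %d alternative position(s)%s\n",
                paste(f$taxa, collapse = ","), f$node_gain,
                length(f$alternative_positions),
                if (f$exclusion_recommended) " [exclude]" else ""))
  invisible(x)
}

prune_trees <- function(trees, taxa) {
  out <- lapply(trees, function(tr) {
    r <- ape::drop.tip(tr, taxa)
    attr(r, "rooted") <- isTRUE(attr(tr, "rooted")) || ape::is.rooted(tr)
    r
  })
  class(out) <- "multiPhylo"
  out
}

## Distinct sister groups (restricted to the remaining leaves) that a
## candidate attaches to across the trees.
attachment_positions <- function(trees, cand) {
  keep <- setdiff(sort(trees[[1]]$tip.label), cand)
  pos <- unique(unlist(lapply(trees, function(tr) {
    sis <- sister_group(tr, cand)
    if (is.null(sis)) return(NULL)
    paste(intersect(keep, sis), collapse = ",")
  })))
  pos[nzchar(pos)]
}

## Leaf set of the sister of the smallest clade containing `cand`.
sister_group <- function(tr, cand) {
  n <- length(tr$tip.label)
  tips <- match(cand, tr$tip.label)
  if (anyNA(tips)) return(NULL)
  node <- if (length(tips) == 1) tips else ape::getMRCA(tr, cand)
  parent <- tr$edge[tr$edge[, 2] == node, 1]
  if (length(parent) == 0) return(NULL)
  kids <- tr$edge[tr$edge[, 1] == parent, 2]
  kids <- setdiff(kids, node)
  unlist(lapply(kids, function(k) tips_below(tr, k)))
}

tips_below <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(tr$tip.label[node])
  ape::extract.clade(tr, node)$tip.label
}

#' Pruned strict consensus
#'
#' Strict consensus computed after removing the given taxa from every input
#' tree (degree-2 nodes suppressed).
#'
#' @param trees `multiPhylo` over one leaf set.
#' @param prune character vector of taxa to remove (may be empty).
#' @return A `phylo`.
#' @export
pruned_strict_consensus <- function(trees, prune = character(0)) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  taxa <- check_same_leaves(trees)
  if (!all(prune %in% taxa))
    stop("prune taxa not in the trees: ",
         paste(setdiff(prune, taxa), collapse = ", "))
  if (length(taxa) - length(prune) < 3)
    stop("pruning would leave fewer than 3 leaves")
  if (length(prune) == 0) return(strict_consensus(trees))
  strict_consensus(prune_trees(trees, prune))
}
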