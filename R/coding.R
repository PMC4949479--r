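#' Source record: one tree or admixture plot with its metadata
#'
#' @param source_id unique identifier of the source.
#' @param kind `"tree"` or `"admixture"`.
#' @param partition one of the data partition labels
#'   (`genomic_tree`, `autosomal_tree`, `y_tree`, `mtdna_tree`, `hla_tree`,
#'   `classical_tree`, `language_tree`, `admixture_genomic`,
#'   `admixture_linguistic`).
#' @param payload a `phylo` tree (for `kind = "tree"`) or a [qmatrix()]
#'   (for `kind = "admixture"`).
#' @param rooted logical; was the source tree published rooted? Admixture
#'   plots carry `rooted = NA` (rooting treatment is decided per scheme).
#' @param has_hominin_outgroup logical; did the source feature great-ape or
#'   archaic-hominin outgroups (used by rooting scheme D)?
#' @return An object of class `source_record`.
#' @export
source_record <- function(source_id, kind = c("tree", "admixture"),
                          partition, payload, rooted = NA,
                          has_hominin_outgroup = FALSE) {
  kind <- match.arg(kind)
  if (!partition %in% setdiff(ALL_PARTITIONS, "classification"))
    stop("unknown partition: ", partition)
  if (kind == "tree") {
    if (!inherits(payload, "phylo")) stop("tree payload must be a phylo object")
    if (partition %in% ADMIX_PARTITIONS)
      stop("tree source cannot carry an admixture partition")
    if (is.na(rooted)) rooted <- isTRUE(attr(payload, "rooted"))
  } else {
    if (!inherits(payload, "qmatrix"))
      stop("admixture payload must be a qmatrix")
    if (!partition %in% ADMIX_PARTITIONS)
      stop("admixture source must carry an admixture partition")
  }
  structure(list(source_id = as.character(source_id), kind = kind,
                 partition = partition, payload = payload,
                 rooted = rooted,
                 has_hominin_outgroup = isTRUE(has_hominin_outgroup)),
            class = "source_record")
}

#' @export
print.source_record <- function(x, ...) {
  cat(sprintf("Source '%s' [%s, %s]%s%s\n", x$source_id, x$kind, x$partition,
              if (isTRUE(x$rooted)) ", rooted" else "",
              if (x$has_hominin_outgroup) ", hominin outgroup" else ""))
  invisible(x)
}

source_taxa <- function(src) {
  if (src$kind == "tree") src$payload$tip.label else src$payload$taxa
}

#' Code a source tree as additive binary characters
#'
#' Baum-Ragan coding: one character per internal node (rooted trees,
#' excluding the root) or per nontrivial split (unrooted trees, with an
#' arbitrary fixed polarity). Taxa descended from the node are scored 1,
#' other taxa present in the tree 0, and taxa of the universe absent from
#' the tree `-` (inapplicable).
#'
#' @param tree a `phylo`; its `rooted` attribute (see [read_newick()])
#'   decides clade versus split coding. Override with `rooted`.
#' @param universe character vector of all taxa of the analysis (defaults to
#'   the tree's own leaves).
#' @param source_id,partition provenance carried into the matrix.
#' @param rooted optional logical overriding the tree's `rooted` attribute.
#' @return A [binary_matrix()] over `universe`.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' code_tree(tr, universe = c("A", "B", "C", "D"))$states
#' @export
code_tree <- function(tree, universe = tree$tip.label,
                      source_id = "tree", partition = "genomic_tree",
                      rooted = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(rooted)) rooted <- isTRUE(attr(tree, "rooted"))
  tips <- tree$tip.label
  if (!all(tips %in% universe))
    stop("tree leaves outside the taxon universe: ",
         paste(setdiff(tips, universe), collapse = ", "))
  empty <- function() {
    binary_matrix(matrix(character(0), nrow = length(universe), ncol = 0,
                         dimnames = list(universe, NULL)),
                  weights = numeric(0),
                  provenance = data.frame(source_id = character(0),
                                          partition = character(0),
                                          node_id = character(0)))
  }
  if (length(tips) < 3) {
    warning("tree with fewer than 3 leaves yields no characters")
    return(empty())
  }
  n <- length(tips)
  groups <- if (rooted) clade_sets(tree) else split_sets(tree)
  maxsz <- if (rooted) n - 1L else n - 2L
  groups <- groups[vapply(groups, length, 1L) >= 2L &
                   vapply(groups, length, 1L) <= maxsz]
  if (length(groups) == 0) return(empty())
  states <- matrix("-", nrow = length(universe), ncol = length(groups),
                   dimnames = list(universe, NULL))
  states[tips, ] <- "0"
  for (j in seq_along(groups)) states[groups[[j]], j] <- "1"
  binary_matrix(states, weights = 1,
                provenance = data.frame(
                  source_id = source_id, partition = partition,
                  node_id = sprintf("nd%02d", seq_along(groups)),
                  stringsAsFactors = FALSE))
}

#' Admixture coding configuration
#'
#' Cluster membership below `present_threshold` is neglected (coded 0); at
#' or above it the taxon is coded present (1). An optional closed-open
#' borderline band around the threshold codes ambiguous proportions as `?`.
#' The band is off by default (crisp 10% rule).
#'
#' @param present_threshold proportion in (0, 1); default 0.10.
#' @param borderline_band `NULL`, `TRUE` (band of +/- 0.05 around the
#'   threshold), or a numeric `c(lo, hi)` closed-open interval containing
#'   the threshold.
#' @return An object of class `admixture_config`.
#' @export
admixture_config <- function(present_threshold = 0.10,
                             borderline_band = NULL) {
  stopifnot(present_threshold > 0, present_threshold < 1)
  if (isTRUE(borderline_band))
    borderline_band <- c(present_threshold - 0.05, present_threshold + 0.05)
  if (!is.null(borderline_band)) {
    stopifnot(length(borderline_band) == 2,
              borderline_band[1] <= present_threshold,
              borderline_band[2] > present_threshold)
  }
  structure(list(present_threshold = present_threshold,
                 borderline_band = borderline_band),
            class = "admixture_config")
}

#' Code an admixture plot as binary characters
#'
#' One character per cluster: membership at or above the presence threshold
#' is coded 1, below it 0, inside the borderline band `?`; universe taxa
#' absent from the plot are `-`. Constant columns are retained but flagged
#' uninformative downstream.
#'
#' @param q a [qmatrix()].
#' @param cfg an [admixture_config()].
#' @param universe character vector of all analysis taxa.
#' @param source_id,partition provenance.
#' @return A [binary_matrix()].
#' @export
code_admixture <- function(q, cfg = admixture_config(),
                           universe = q$taxa,
                           source_id = "admix",
                           partition = "admixture_genomic") {
  stopifnot(inherits(q, "qmatrix"), inherits(cfg, "admixture_config"))
  if (!all(q$taxa %in% universe))
    stop("Q-matrix taxa outside the taxon universe: ",
         paste(setdiff(q$taxa, universe), collapse = ", "))
  thr <- cfg$present_threshold
  band <- cfg$borderline_band
  coded <- ifelse(q$memberships >= thr, "1", "0")
  if (!is.null(band))
    coded[q$memberships >= band[1] & q$memberships < band[2]] <- "?"
  states <- matrix("-", nrow = length(universe), ncol = q$K,
                   dimnames = list(universe, NULL))
  states[q$taxa, ] <- coded
  binary_matrix(states, weights = 1,
                provenance = data.frame(
                  source_id = source_id, partition = partition,
                  node_id = sprintf("k%02d", seq_len(q$K)),
                  stringsAsFactors = FALSE))
}

#' Maximum-parsimony tree implied by an admixture plot
#'
#' Codes the plot, then runs maximum parsimony on the coded characters alone
#' and returns the strict consensus of the MP trees: the clustering the plot
#' implies as a (typically partly unresolved) unrooted topology. Diagnostic
#' only; the merged supertree analysis uses the coded matrix directly.
#'
#' @param q a [qmatrix()].
#' @param cfg an [admixture_config()].
#' @param search_cfg a [search_config()]; the exhaustive oracle is used when
#'   the taxon count allows it.
#' @return A `phylo` (unrooted; a star when no character is informative,
#'   with attribute `unresolved = TRUE`).
#' @export
implied_admixture_tree <- function(q, cfg = admixture_config(),
                                   search_cfg = search_config()) {
  m <- code_admixture(q, cfg)
  star <- function() {
    tr <- ape::read.tree(text = paste0("(", paste(q$taxa, collapse = ","), ");"))
    attr(tr, "unresolved") <- TRUE
    tr
  }
  if (!any(is_informative(m))) return(star())
  res <- if (length(q$taxa) <= search_cfg$exhaustive_limit)
    exhaustive_search(m, exhaustive_limit = search_cfg$exhaustive_limit)
  else heuristic_search(m, search_cfg)
  strict_consensus(res$mp_trees)
}

#' Apply a rooting scheme by inserting the hypothetical all-0 outgroup
#'
#' Adds the taxon `ALL0` scored 0 for every character whose source is
#' treated as rooted under the scheme, and `?` otherwise, so unrooted
#' sources constrain grouping but not polarity:
#' * `"A"` - all rooted source trees and all admixture plots rooted;
#' * `"B"` - only rooted source trees;
#' * `"C"` - only rooted genetic/genomic trees;
#' * `"D"` - only sources featuring great-ape / archaic-hominin outgroups.
#'
#' @param m a merged [binary_matrix()] whose provenance links every
#'   character to an entry of `sources`.
#' @param sources list of [source_record()]s.
#' @param scheme one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return The matrix with the extra `ALL0` taxon.
#' @export
apply_rooting <- function(m, sources, scheme = c("A", "B", "C", "D")) {
  if (!is.character(scheme) || !scheme[1] %in% c("A", "B", "C", "D"))
    stop("unknown rooting scheme: ", paste(scheme[1], collapse = ""))
  scheme <- scheme[1]
  stopifnot(inherits(m, "binary_matrix"))
  ids <- vapply(sources, `[[`, "", "source_id")
  names(sources) <- ids
  miss <- setdiff(unique(m$provenance$source_id), ids)
  if (length(miss))
    stop("characters with no matching source record: ",
         paste(miss, collapse = ", "))
  treated <- vapply(seq_len(ncol(m$states)), function(j) {
    src <- sources[[m$provenance$source_id[j]]]
    switch(scheme,
           A = (src$kind == "tree" && isTRUE(src$rooted)) ||
               src$kind == "admixture",
           B = src$kind == "tree" && isTRUE(src$rooted),
           C = src$kind == "tree" && isTRUE(src$rooted) &&
               src$partition %in% GENETIC_TREE_PARTITIONS,
           D = src$has_hominin_outgroup)
  }, TRUE)
  row0 <- ifelse(treated, "0", "?")
  states <- rbind(m$states, matrix(row0, nrow = 1,
                                   dimnames = list(ALL0, NULL)))
  binary_matrix(states, m$weights, m$provenance)
}

#' Apply a weighting scheme to the data partitions
#'
#' Reproduces the four weighting schemes of the sensitivity grid:
#' * `1` - all partitions weighted equally (weight 1);
#' * `2` - all trees upweighted by `factor` relative to admixture plots;
#' * `3` - genetic/genomic trees upweighted by `factor` relative to language
#'   trees and all admixture plots;
#' * `4` - genomic trees upweighted by `factor` relative to all remaining
#'   partitions.
#' With `deactivate = TRUE` the low class is weighted 0 (characters ignored)
#' instead of 1, the variant used to check that downweighting alone is
#' sufficient to suppress a partition.
#'
#' @param m a [binary_matrix()] whose provenance carries partition labels.
#' @param scheme integer 1-4.
#' @param factor upweighting factor (default 1000).
#' @param deactivate logical.
#' @return The reweighted matrix (states untouched).
#' @export
apply_weights <- function(m, scheme, factor = 1000, deactivate = FALSE) {
  stopifnot(inherits(m, "binary_matrix"))
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:4) stop("unknown weighting scheme: ", scheme)
  stopifnot(factor > 0)
  part <- m$provenance$partition
  high <- switch(scheme,
                 `1` = rep(TRUE, length(part)),
                 `2` = part %in% TREE_PARTITIONS,
                 `3` = part %in% GENETIC_TREE_PARTITIONS,
                 `4` = part == "genomic_tree")
  w <- ifelse(high, if (scheme == 1) 1 else factor,
              if (deactivate) 0 else 1)
  binary_matrix(m$states, w, m$provenance)
}

#' Code all sources and merge into one matrix
#'
#' Convenience wrapper: codes every source record over the union of their
#' taxa (or a supplied universe) and merges the partial matrices.
#'
#' @param sources list of [source_record()]s.
#' @param universe optional taxon universe.
#' @param admix_cfg an [admixture_config()].
#' @return A merged [binary_matrix()].
#' @export
code_sources <- function(sources, universe = NULL,
                         admix_cfg = admixture_config()) {
  stopifnot(length(sources) > 0)
  if (is.null(universe))
    universe <- unique(unlist(lapply(sources, source_taxa)))
  mats <- lapply(sources, function(src) {
    if (src$kind == "tree")
      code_tree(src$payload, universe, source_id = src$source_id,
                partition = src$partition, rooted = src$rooted)
    else
      code_admixture(src$payload, admix_cfg, universe,
                     source_id = src$source_id, partition = src$partition)
  })
  mats <- mats[vapply(mats, function(m) ncol(m$states) > 0, TRUE)]
  if (length(mats) == 0) stop("no source yielded any characters")
  merge_matrices(mats)
}
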