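#' Configuration for a full supertree analysis
#'
#' @param sources list of [source_record()]s (e.g. from a scenario or
#'   [read_scenario()]).
#' @param groups optional named list of taxon sets whose status
#'   (monophyletic / paraphyletic-or-unresolved / polyphyletic) is tabulated
#'   per parameter set.
#' @param grid parameter grid (default the full 16-cell grid).
#' @param search a [search_config()].
#' @param exclusion_threshold wildcard node-gain threshold for exclusion
#'   (default 5).
#' @param admixture an [admixture_config()].
#' @param constraint classification (as from [classification_matrix()]) used
#'   by [constrained_supertree()]; optional.
#' @param constraint_weight weight factor for constraint characters
#'   (default 1000).
#' @param factor partition upweighting factor (default 1000).
#' @param out_dir optional directory where reports are written.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(sources, groups = NULL,
                            grid = build_parameter_grid(),
                            search = search_config(),
                            exclusion_threshold = 5,
                            admixture = admixture_config(),
                            constraint = NULL,
                            constraint_weight = 1000,
                            factor = 1000,
                            out_dir = NULL, seed = 1L) {
  stopifnot(length(sources) >= 1)
  search$seed <- as.integer(seed)
  structure(list(sources = sources, groups = groups, grid = grid,
                 search = search,
                 exclusion_threshold = exclusion_threshold,
                 admixture = admixture, constraint = constraint,
                 constraint_weight = constraint_weight, factor = factor,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full supertree analysis
#'
#' Executes the sensitivity grid, identifies wildcard taxa on every cell's
#' MP set, applies the node-gain exclusion rule, reruns the grid on the
#' pruned dataset, and reports consensus trees, pairwise SPR comparisons
#' across cells, wildcard records and the group-status table. Fully
#' reproducible from the configuration and seed.
#'
#' @param cfg an [analysis_config()].
#' @return An object of class `mrp_analysis`: list with `initial`
#'   (sensitivity result), `wildcards` (per-cell reports), `excluded`
#'   (taxa removed by the exclusion rule), `final` (sensitivity result on
#'   the pruned data), `comparisons` (pairwise cell comparisons),
#'   `group_status` (data frame), `seed`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  initial <- run_sensitivity(cfg$sources, cfg$grid, cfg$search,
                             admix_cfg = cfg$admixture, factor = cfg$factor)
  wildcards <- lapply(initial, function(cell) {
    trees <- cell$search$mp_trees
    if (length(trees) < 2)  # a single MP tree cannot exhibit instability
      return(structure(list(flagged = list(), pruned_taxa = character(0),
                            consensus = trees[[1]],
                            baseline_nodes = n_resolved_nodes(trees[[1]]),
                            final_nodes = n_resolved_nodes(trees[[1]])),
                       class = "wildcard_report"))
    identify_wildcards(trees, min_gain = 1,
                       exclusion_threshold = cfg$exclusion_threshold)
  })
  ## aggregate per candidate across parameter sets
  agg <- list()
  for (lab in names(wildcards)) {
    for (f in wildcards[[lab]]$flagged) {
      k <- set_key(f$taxa)
      if (is.null(agg[[k]]))
        agg[[k]] <- list(taxa = f$taxa, flagged_sets = character(0),
                         node_gain = integer(0))
      agg[[k]]$flagged_sets <- c(agg[[k]]$flagged_sets, lab)
      agg[[k]]$node_gain <- c(agg[[k]]$node_gain, f$node_gain)
    }
  }
  excluded <- character(0)
  for (a in agg)
    if (max(a$node_gain) >= cfg$exclusion_threshold)
      excluded <- c(excluded, a$taxa)
  excluded <- sort(unique(excluded))
  final_sources <- if (length(excluded) > 0)
    prune_sources(cfg$sources, excluded) else cfg$sources
  final <- run_sensitivity(final_sources, cfg$grid, cfg$search,
                           admix_cfg = cfg$admixture, factor = cfg$factor)
  comparisons <- cell_comparisons(final)
  gs <- NULL
  if (!is.null(cfg$groups)) {
    rows <- list()
    for (g in names(cfg$groups)) {
      grp <- setdiff(cfg$groups[[g]], excluded)
      for (lab in names(final)) {
        tr <- final[[lab]]$strict
        st <- if (length(grp) >= 2 && length(grp) < length(tr$tip.label))
          group_status(tr, grp) else NA_character_
        rows <- c(rows, list(data.frame(group = g, parameter_set = lab,
                                        status = st,
                                        stringsAsFactors = FALSE)))
      }
    }
    gs <- do.call(rbind, rows)
  }
  out <- structure(list(initial = initial, wildcards = wildcards,
                        wildcard_summary = agg, excluded = excluded,
                        final = final, comparisons = comparisons,
                        group_status = gs, seed = cfg$seed),
                   class = "mrp_analysis")
  if (!is.null(cfg$out_dir)) write_analysis(out, cfg$out_dir)
  out
}

#' @export
print.mrp_analysis <- function(x, ...) {
  cat(sprintf("Supertree analysis: %d parameter set(s), seed %d\n",
              length(x$final), x$seed))
  cat(sprintf("  excluded wildcards: %s\n",
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none"))
  if (nrow(x$comparisons) > 0)
    cat(sprintf("  pairwise similarity: %.0f-%.0f%%\n",
                min(x$comparisons$similarity_pct),
                max(x$comparisons$similarity_pct)))
  invisible(x)
}

prune_sources <- function(sources, taxa) {
  out <- list()
  for (src in sources) {
    if (src$kind == "tree") {
      keep <- setdiff(src$payload$tip.label, taxa)
      if (length(keep) < 3) next
      tr <- ape::keep.tip(src$payload, keep)
      attr(tr, "rooted") <- isTRUE(src$rooted)
      src$payload <- tr
    } else {
      keep <- setdiff(src$payload$taxa, taxa)
      if (length(keep) < 2) next
      src$payload <- qmatrix(keep,
                             src$payload$memberships[keep, , drop = FALSE])
    }
    out <- c(out, list(src))
  }
  names(out) <- vapply(out, `[[`, "", "source_id")
  out
}

cell_comparisons <- function(cells) {
  labs <- names(cells)
  rows <- list()
  if (length(labs) >= 2) {
    for (i in seq_len(length(labs) - 1)) {
      for (j in (i + 1):length(labs)) {
        cmp <- spr_distance(cells[[i]]$strict, cells[[j]]$strict)
        rows <- c(rows, list(data.frame(
          set1 = labs[i], set2 = labs[j], d_spr = cmp$d_spr,
          exact = cmp$exact, similarity_pct = cmp$similarity_pct,
          rf = cmp$rf, stringsAsFactors = FALSE)))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(set1 = character(0), set2 = character(0),
                      d_spr = numeric(0), exact = logical(0),
                      similarity_pct = numeric(0), rf = numeric(0)))
  do.call(rbind, rows)
}

#' Supertree constrained by a categorical classification
#'
#' Implements topological constraints the way the supertree literature does
#' for linguistic classifications: one binary character per family, appended
#' to the merged matrix at a large weight (default 1000x) so that parsimony
#' enforces every fully scored family as a clade unless a heavier character
#' conflicts; taxa scored `?` (language-shift populations) attach freely by
#' the genetic signal. All partitions are rooted by the all-0 outgroup
#' (scheme A); linguistic source partitions are upweighted together with the
#' classification.
#'
#' @param sources list of [source_record()]s.
#' @param classification result of [classification_matrix()] /
#'   [generate_classification()], or a bare [binary_matrix()].
#' @param search_cfg a [search_config()].
#' @param admix_cfg an [admixture_config()].
#' @param factor constraint weight factor (default 1000).
#' @return A `search_result` with rooted `mp_trees` (outgroup dropped).
#' @export
constrained_supertree <- function(sources, classification,
                                  search_cfg = search_config(),
                                  admix_cfg = admixture_config(),
                                  factor = 1000) {
  cls <- if (inherits(classification, "binary_matrix")) classification
  else classification$matrix
  check_constraint_conflicts(cls)
  merged <- code_sources(sources, admix_cfg = admix_cfg)
  universe <- unique(c(merged$taxa, cls$taxa))
  pad <- function(m) {
    out <- matrix("-", nrow = length(universe), ncol = ncol(m$states),
                  dimnames = list(universe, colnames(m$states)))
    out[m$taxa, ] <- m$states
    binary_matrix(out, m$weights, m$provenance)
  }
  merged <- pad(merged)
  cls <- pad(cls)
  merged <- apply_rooting(merged, sources, "A")
  lingu <- merged$provenance$partition %in%
    c("language_tree", "admixture_linguistic")
  w <- ifelse(lingu, factor, 1)
  merged <- binary_matrix(merged$states, w, merged$provenance)
  ## constraint characters: rooted statements, outgroup scored 0
  cls_states <- rbind(cls$states, matrix("0", nrow = 1, ncol = ncol(cls$states),
                                         dimnames = list(ALL0, NULL)))
  cls <- binary_matrix(cls_states, rep(factor, ncol(cls_states)),
                       cls$provenance)
  full <- merge_matrices(list(merged, cls))
  res <- heuristic_search(full, search_cfg)
  res$mp_trees <- root_at_all0(res$mp_trees)
  res
}

## Pairwise hard-conflict check between constraint characters: two rooted
## binary characters conflict iff, among taxa scored in both, all four
## state combinations occur.
check_constraint_conflicts <- function(m) {
  nc <- ncol(m$states)
  if (nc < 2) return(invisible(TRUE))
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      a <- m$states[, i]
      b <- m$states[, j]
      ok <- a %in% c("0", "1") & b %in% c("0", "1")
      pat <- unique(paste0(a[ok], b[ok]))
      if (all(c("00", "01", "10", "11") %in% pat))
        warning(sprintf("constraint characters '%s' and '%s' are mutually incompatible; the heaviest compatible set will win",
                        colnames(m$states)[i], colnames(m$states)[j]))
    }
  }
  invisible(TRUE)
}

#' Status of a named group on a (possibly unresolved) tree
#'
#' * `"monophyletic"`: some node's leaf set equals the group exactly.
#' * `"paraphyletic_or_unresolved"`: the group's membership split is
#'   compatible with every split of the topology, i.e. the group is a clade
#'   under some rooting of some resolution (one character step), but not a
#'   clade here.
#' * `"polyphyletic"`: the membership character requires at least two steps
#'   however the polytomies are resolved.
#'
#' @param tree a `phylo`.
#' @param group character vector of taxa, `2 <= |group| < n`.
#' @return One of the three status strings.
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),C),D);")
#' group_status(tr, c("C", "D"))
#' @export
group_status <- function(tree, group) {
  leaves <- sort(tree$tip.label)
  group <- sort(unique(group))
  if (!all(group %in% leaves)) stop("group taxa missing from the tree")
  if (length(group) < 2 || length(group) >= length(leaves))
    stop("group must contain between 2 and n-1 taxa")
  cl <- clade_sets(tree)
  keys <- vapply(cl, set_key, "")
  if (set_key(group) %in% keys) return("monophyletic")
  compat <- all(vapply(cl, function(s) splits_compatible(group, s, leaves),
                       TRUE))
  if (compat) "paraphyletic_or_unresolved" else "polyphyletic"
}

#' Fit of a classification on a supertree
#'
#' Per-family consistency and retention indices with the size-corrected
#' minimum (`CI_min = 1/N`) and the excess fit `CI - CI_min`; families with
#' fewer than two scored members are excluded with a note. Ensemble CI/RI
#' cover the informative families.
#'
#' @param tree a `phylo` (the supertree).
#' @param classification as in [constrained_supertree()].
#' @return An object of class `classification_fit`: list with `per_family`
#'   (sorted by CI), `excluded_families`, `ensemble_CI`, `ensemble_RI`.
#' @export
fit_classification <- function(tree, classification) {
  cls <- if (inherits(classification, "binary_matrix")) classification
  else classification$matrix
  common <- intersect(cls$taxa, tree$tip.label)
  cls2 <- binary_matrix(cls$states[common, , drop = FALSE], cls$weights,
                        cls$provenance)
  scored <- colSums(cls2$states == "1")
  drop <- scored < 2
  note <- colnames(cls2$states)[drop]
  keep <- which(!drop)
  if (length(keep) == 0) stop("no family has two or more scored members")
  cls2 <- binary_matrix(cls2$states[, keep, drop = FALSE],
                        cls2$weights[keep],
                        cls2$provenance[keep, , drop = FALSE])
  fit <- character_fit(tree, cls2)
  per <- fit$per_character
  names(per)[names(per) == "character"] <- "family"
  per$excess <- per$CI - per$CI_min
  per <- per[order(-per$CI, per$family), ]
  rownames(per) <- NULL
  structure(list(per_family = per, excluded_families = note,
                 ensemble_CI = fit$ensemble_CI,
                 ensemble_RI = fit$ensemble_RI),
            class = "classification_fit")
}

#' @export
print.classification_fit <- function(x, ...) {
  cat(sprintf("Classification fit: %d families, ensemble CI %.3f, RI %.3f\n",
              nrow(x$per_family), x$ensemble_CI, x$ensemble_RI))
  if (length(x$excluded_families))
    cat("  excluded (fewer than 2 scored members):",
        paste(x$excluded_families, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an analysis to a deterministic report bundle
#'
#' Consensus trees as Newick, comparisons and group status as TSV, wildcard
#' and summary information as JSON. Identical analyses produce byte-identical
#' bundles.
#'
#' @param x an `mrp_analysis`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(x$final)) {
    write_newick(x$final[[lab]]$strict,
                 file.path(dir, paste0("strict_", lab, ".nwk")))
    write_newick(x$final[[lab]]$semistrict,
                 file.path(dir, paste0("semistrict_", lab, ".nwk")))
  }
  write.table(x$comparisons, file.path(dir, "comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$group_status))
    write.table(x$group_status, file.path(dir, "group_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  wc <- lapply(names(x$wildcards), function(lab) {
    w <- x$wildcards[[lab]]
    list(parameter_set = lab,
         flagged = lapply(w$flagged, function(f)
           list(taxa = f$taxa, node_gain = f$node_gain,
                alternative_positions = f$alternative_positions,
                exclusion_recommended = f$exclusion_recommended)))
  })
  jsonlite::write_json(list(seed = x$seed, excluded = x$excluded,
                            scores = lapply(x$final, function(cell)
                              cell$search$best_score),
                            wildcards = wc),
                       file.path(dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
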