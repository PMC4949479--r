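#' Generate a random rooted binary "true" population tree
#'
#' Yule-style growth: starting from two lineages, a uniformly chosen extant
#' leaf is split until `n_taxa` leaves exist. Leaves are labelled `P001`,
#' `P002`, ... in traversal order. Deterministic per seed.
#'
#' @param n_taxa number of leaves (at least 4).
#' @param seed integer seed.
#' @return A rooted binary `phylo` with attribute `rooted = TRUE`.
#' @export
generate_true_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  with_seed(seed, {
    kids <- list()                 # node id -> children ids
    next_id <- 3L
    kids[["1"]] <- c(2L, 3L)
    leaves <- c(2L, 3L)
    while (length(leaves) < n_taxa) {
      pick <- leaves[sample.int(length(leaves), 1L)]
      a <- next_id + 1L
      b <- next_id + 2L
      next_id <- b
      kids[[as.character(pick)]] <- c(a, b)
      leaves <- c(setdiff(leaves, pick), a, b)
    }
    counter <- new.env(parent = emptyenv())
    counter$i <- 0L
    emit <- function(id) {
      ch <- kids[[as.character(id)]]
      if (is.null(ch)) {
        counter$i <- counter$i + 1L
        return(sprintf("P%03d", counter$i))
      }
      paste0("(", emit(ch[1]), ",", emit(ch[2]), ")")
    }
    txt <- paste0(emit(1L), ";")
    tr <- ape::read.tree(text = txt)
    attr(tr, "rooted") <- TRUE
    tr
  })
}

## One random rooted NNI move: pick an internal non-root node c with an
## internal parent p (p may be the root), and swap one child of c with c's
## sibling. Changes exactly one clade.
rooted_nni <- function(tr) {
  n <- length(tr$tip.label)
  root <- n + 1L
  internal <- setdiff(unique(tr$edge[, 1]), root)
  internal <- internal[internal > n]
  if (length(internal) == 0) return(tr)
  c_node <- internal[sample.int(length(internal), 1L)]
  p <- tr$edge[tr$edge[, 2] == c_node, 1]
  sibs <- setdiff(tr$edge[tr$edge[, 1] == p, 2], c_node)
  s <- sibs[sample.int(length(sibs), 1L)]
  ch <- tr$edge[tr$edge[, 1] == c_node, 2]
  x <- ch[sample.int(length(ch), 1L)]
  e <- tr$edge
  e[e[, 1] == p & e[, 2] == s, ] <- c(c_node, s)
  e[e[, 1] == c_node & e[, 2] == x, ] <- c(p, x)
  tr$edge <- e
  tr <- ape::read.tree(text = ape::write.tree(tr))  # renormalize ordering
  tr
}

## Attach a new leaf halfway along the branch above `where` (node or tip).
attach_leaf <- function(tr, leaf, where) {
  tr$edge.length <- rep(1, nrow(tr$edge))
  out <- ape::bind.tree(tr, ape::read.tree(text = paste0("(", leaf, ":1);")),
                        where = where, position = 0.5)
  out$edge.length <- NULL
  ape::read.tree(text = ape::write.tree(out))
}

## Prune a leaf and reattach it on a uniformly chosen edge (leaf SPR);
## used to plant rogue taxa.
leaf_spr <- function(tr, leaf) {
  rest <- ape::drop.tip(tr, leaf)
  ne <- nrow(rest$edge)
  target <- sample.int(ne + 1L, 1L)  # +1: attach above the root
  if (target > ne) {
    txt <- paste0("(", sub(";$", "", ape::write.tree(rest)), ",", leaf, ");")
    out <- ape::read.tree(text = txt)
  } else {
    out <- attach_leaf(rest, leaf, rest$edge[target, 2])
  }
  attr(out, "rooted") <- isTRUE(attr(tr, "rooted"))
  out
}

#' Sample a noisy partial source tree from the true tree
#'
#' Emulates a published source: restrict the true tree to a random taxon
#' subset (`keep_fraction`, at least 4 taxa), perturb it with `n_nni` random
#' nearest-neighbor interchanges, reattach any planted rogue taxa at random
#' positions, and tag the result with a data partition.
#'
#' @param true_tree rooted binary `phylo`.
#' @param keep_fraction fraction of taxa retained, in (0, 1].
#' @param n_nni number of random NNI perturbations (topological noise).
#' @param partition data partition label.
#' @param rooted logical; is the source presented as rooted?
#' @param has_hominin_outgroup logical flag for rooting scheme D.
#' @param rogue_taxa taxa to reattach at random positions when sampled.
#' @param seed integer seed.
#' @param source_id identifier (default derived from partition and seed).
#' @return A [source_record()] of kind `"tree"`.
#' @export
sample_source_tree <- function(true_tree, keep_fraction = 0.5, n_nni = 0,
                               partition = "genomic_tree", rooted = TRUE,
                               has_hominin_outgroup = FALSE,
                               rogue_taxa = character(0),
                               seed = 1L,
                               source_id = paste0(partition, "_s", seed)) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1, n_nni >= 0)
  taxa <- true_tree$tip.label
  k <- max(4L, round(keep_fraction * length(taxa)))
  if (k > length(taxa)) stop("true tree has fewer than 4 leaves")
  with_seed(seed, {
    keep <- sort(sample(taxa, k))
    tr <- ape::keep.tip(true_tree, keep)
    attr(tr, "rooted") <- TRUE
    for (i in seq_len(n_nni)) tr <- rooted_nni(tr)
    for (rg in intersect(rogue_taxa, keep))
      tr <- leaf_spr(tr, rg)
    attr(tr, "rooted") <- isTRUE(rooted)
    source_record(source_id, "tree", partition, tr, rooted = rooted,
                  has_hominin_outgroup = has_hominin_outgroup)
  })
}

## Cut a rooted tree into K leaf-disjoint blocks by repeatedly splitting the
## largest splittable block into the children of its root.
tree_k_cut <- function(tree, K) {
  n <- length(tree$tip.label)
  if (K < 2 || K > n) stop("impossible K: must be between 2 and ", n)
  blocks <- list(tree)
  block_tips <- list(tree$tip.label)
  while (length(blocks) < K) {
    sizes <- vapply(block_tips, length, 1L)
    splittable <- which(sizes >= 2)
    if (length(splittable) == 0) stop("impossible K for this tree")
    i <- splittable[which.max(sizes[splittable])]
    tr <- blocks[[i]]
    if (length(tr$tip.label) == 2) {
      parts <- as.list(tr$tip.label)
      newb <- list(NULL, NULL)
      newt <- parts
    } else {
      root <- length(tr$tip.label) + 1L
      ch <- tr$edge[tr$edge[, 1] == root, 2]
      newb <- list()
      newt <- list()
      for (c_ in ch) {
        tips <- tips_below(tr, c_)
        newt <- c(newt, list(tips))
        newb <- c(newb, list(if (length(tips) >= 2)
          ape::keep.tip(tr, tips) else NULL))
      }
    }
    blocks <- c(blocks[-i], newb)
    block_tips <- c(block_tips[-i], newt)
  }
  block_tips
}

#' Generate a synthetic admixture plot from the true tree
#'
#' Cuts the true tree into K leaf-disjoint clades and draws each taxon's
#' membership row from a Dirichlet distribution centered on its clade
#' indicator with concentration `alpha` (larger is crisper;
#' `alpha = Inf` gives exact indicators). Planted admixed taxa get 50/50
#' mixtures of their own and one other cluster.
#'
#' @param true_tree rooted binary `phylo`.
#' @param K cluster count (2 to the number of obtainable clades).
#' @param alpha Dirichlet concentration of the own-cluster component
#'   (default 100; `Inf` for the noise-free limit).
#' @param admixed_taxa taxa planted as 50/50 two-cluster mixtures.
#' @param seed integer seed.
#' @param partition admixture partition label.
#' @param source_id identifier.
#' @return A [source_record()] of kind `"admixture"`.
#' @export
generate_admixture_plot <- function(true_tree, K = 3, alpha = 100,
                                    admixed_taxa = character(0), seed = 1L,
                                    partition = "admixture_genomic",
                                    source_id = paste0("admix_s", seed)) {
  blocks <- tree_k_cut(true_tree, K)
  taxa <- true_tree$tip.label
  own <- integer(length(taxa))
  for (b in seq_along(blocks)) own[taxa %in% blocks[[b]]] <- b
  with_seed(seed, {
    mem <- matrix(0, nrow = length(taxa), ncol = K)
    for (i in seq_along(taxa)) {
      conc <- rep(1, K)
      conc[own[i]] <- alpha
      if (taxa[i] %in% admixed_taxa) {
        partner <- sample(setdiff(seq_len(K), own[i]), 1L)
        conc <- rep(1, K)
        conc[c(own[i], partner)] <- alpha / 2
      }
      if (is.infinite(alpha)) {
        row <- as.numeric(conc == max(conc))
        row <- row / sum(row)
      } else {
        row <- rgamma(K, shape = conc, rate = 1)
        row <- row / sum(row)
      }
      mem[i, ] <- row
    }
    q <- qmatrix(taxa, mem)
    source_record(source_id, "admixture", partition, q)
  })
}

#' Generate a categorical classification over the true tree
#'
#' Assigns `n_families` family labels as clades of the true tree (so a
#' noise-free classification is perfectly consistent with it), then
#' reassigns a `misfit_rate` fraction of taxa to wrong families (emulating
#' gene-language discordance). `unknown_taxa` (e.g. language-shift
#' populations) are scored `?` in every family character.
#'
#' @param true_tree rooted binary `phylo`.
#' @param n_families number of families (at least 2).
#' @param misfit_rate fraction of taxa reassigned to a wrong family,
#'   in `[0, 1)`.
#' @param unknown_taxa taxa scored unknown.
#' @param seed integer seed.
#' @return List with `table` (data frame `taxon`, `family`) and `matrix`
#'   (a [binary_matrix()] with one character per family, partition
#'   `"classification"`).
#' @export
generate_classification <- function(true_tree, n_families = 4,
                                    misfit_rate = 0,
                                    unknown_taxa = character(0), seed = 1L) {
  stopifnot(n_families >= 2, misfit_rate >= 0, misfit_rate < 1)
  blocks <- tree_k_cut(true_tree, n_families)
  taxa <- true_tree$tip.label
  fam <- character(length(taxa))
  for (b in seq_along(blocks))
    fam[taxa %in% blocks[[b]]] <- sprintf("F%02d", b)
  with_seed(seed, {
    n_mis <- floor(misfit_rate * length(taxa))
    if (n_mis > 0) {
      mis <- sample(setdiff(taxa, unknown_taxa), n_mis)
      for (t in mis) {
        i <- match(t, taxa)
        fam[i] <- sample(setdiff(unique(fam), fam[i]), 1L)
      }
    }
    fam[taxa %in% unknown_taxa] <- NA_character_
    classification_matrix(data.frame(taxon = taxa, family = fam,
                                     stringsAsFactors = FALSE))
  })
}

#' Build family characters from a classification table
#'
#' One binary character per family: members 1, other classified taxa 0,
#' unclassified (`NA` or `"?"`) taxa `?`.
#'
#' @param df data frame with columns `taxon`, `family`.
#' @param universe optional taxon universe (extra taxa coded `-`).
#' @return List with `table` and `matrix` as in [generate_classification()].
#' @export
classification_matrix <- function(df, universe = df$taxon) {
  stopifnot(all(c("taxon", "family") %in% names(df)))
  fam <- df$family
  fam[fam %in% "?"] <- NA_character_
  fams <- sort(unique(fam[!is.na(fam)]))
  states <- matrix("-", nrow = length(universe), ncol = length(fams),
                   dimnames = list(universe, fams))
  for (j in seq_along(fams)) {
    states[df$taxon, j] <- ifelse(is.na(fam), "?",
                                  ifelse(fam == fams[j], "1", "0"))
  }
  m <- binary_matrix(states, weights = 1,
                     provenance = data.frame(
                       source_id = "classification",
                       partition = "classification",
                       node_id = fams, stringsAsFactors = FALSE))
  list(table = df, matrix = m)
}

#' Generate a full synthetic supertree scenario with known ground truth
#'
#' Emulates the structure of a compiled supertree dataset: a true rooted
#' binary tree, many partially overlapping noisy source trees spread over
#' the data partitions (the partition census mirrors the proportions of
#' published source compilations: HLA and other genetic trees dominate,
#' language trees are fewer, about 15% of sources are admixture plots),
#' admixture Q-matrices derived from tree cuts with Dirichlet noise, planted
#' rogue and admixed taxa, and a family classification. The `manifest`
#' element suffices to regenerate the scenario bit-identically via
#' [regenerate_scenario()].
#'
#' @param n_taxa leaves of the true tree (default 30).
#' @param n_sources total source count (default 40).
#' @param keep_fraction taxon coverage per source (default 0.5).
#' @param n_nni NNI noise per source tree (default 1).
#' @param admix_fraction fraction of sources that are admixture plots
#'   (default 0.15).
#' @param alpha Dirichlet concentration for plots (default 100).
#' @param n_rogues number of planted rogue taxa (default 0).
#' @param n_admixed number of planted admixed taxa (default 0).
#' @param n_families classification families (default 4).
#' @param misfit_rate classification misfit fraction (default 0).
#' @param n_unknown taxa scored unknown in the classification (default 0).
#' @param rooted_fraction fraction of tree sources presented rooted
#'   (default 0.7).
#' @param hominin_fraction fraction of rooted genetic sources carrying
#'   great-ape/archaic outgroups (default 0.3).
#' @param seed integer seed.
#' @return An object of class `mrp_scenario`: list with `true_tree`,
#'   `sources`, `classification`, `planted_rogues`, `planted_admixed`,
#'   `manifest`.
#' @export
generate_scenario <- function(n_taxa = 30, n_sources = 40,
                              keep_fraction = 0.5, n_nni = 1,
                              admix_fraction = 0.15, alpha = 100,
                              n_rogues = 0, n_admixed = 0,
                              n_families = 4, misfit_rate = 0,
                              n_unknown = 0,
                              rooted_fraction = 0.7,
                              hominin_fraction = 0.3,
                              seed = 1L) {
  manifest <- as.list(environment())
  true_tree <- generate_true_tree(n_taxa, seed = derive_seed(seed, 1))
  taxa <- true_tree$tip.label
  n_plots <- round(admix_fraction * n_sources)
  n_trees <- n_sources - n_plots
  ## partition census proportional to a typical compiled dataset
  census <- c(genomic_tree = 51, autosomal_tree = 26, y_tree = 9,
              mtdna_tree = 25, hla_tree = 75, classical_tree = 27,
              language_tree = 44)
  counts <- round(census / sum(census) * n_trees)
  while (sum(counts) > n_trees) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < n_trees) counts[which.max(census)] <-
    counts[which.max(census)] + 1L
  meta <- with_seed(derive_seed(seed, 2), {
    rogues <- if (n_rogues > 0) sample(taxa, n_rogues) else character(0)
    admixed <- if (n_admixed > 0)
      sample(setdiff(taxa, rogues), n_admixed) else character(0)
    unknown <- if (n_unknown > 0)
      sample(setdiff(taxa, c(rogues, admixed)), n_unknown) else character(0)
    list(rogues = sort(rogues), admixed = sort(admixed),
         unknown = sort(unknown))
  })
  sources <- list()
  idx <- 0L
  for (p in names(counts)) {
    for (i in seq_len(counts[[p]])) {
      idx <- idx + 1L
      sseed <- derive_seed(seed, 100 + idx)
      flags <- with_seed(derive_seed(seed, 500 + idx), {
        rooted <- runif(1) < rooted_fraction
        hom <- rooted && p != "language_tree" &&
          runif(1) < hominin_fraction
        c(rooted, hom)
      })
      src <- sample_source_tree(true_tree, keep_fraction, n_nni,
                                partition = p, rooted = flags[1],
                                has_hominin_outgroup = flags[2],
                                rogue_taxa = meta$rogues, seed = sseed,
                                source_id = sprintf("%s_%02d", p, i))
      sources <- c(sources, list(src))
    }
  }
  for (i in seq_len(n_plots)) {
    idx <- idx + 1L
    K <- 2L + (i %% 3L)  # K cycles over 3, 4, 2 -> varied granularity
    src <- generate_admixture_plot(true_tree, K = min(K, n_taxa %/% 2),
                                   alpha = alpha,
                                   admixed_taxa = meta$admixed,
                                   seed = derive_seed(seed, 100 + idx),
                                   source_id = sprintf("admix_%02d", i))
    sources <- c(sources, list(src))
  }
  names(sources) <- vapply(sources, `[[`, "", "source_id")
  classification <- generate_classification(true_tree, n_families,
                                            misfit_rate,
                                            unknown_taxa = meta$unknown,
                                            seed = derive_seed(seed, 3))
  structure(list(true_tree = true_tree, sources = sources,
                 classification = classification,
                 planted_rogues = meta$rogues,
                 planted_admixed = meta$admixed,
                 manifest = manifest),
            class = "mrp_scenario")
}

#' Regenerate a scenario bit-identically from its manifest
#' @param manifest the `manifest` element of an [generate_scenario()] result.
#' @return An `mrp_scenario`.
#' @export
regenerate_scenario <- function(manifest) do.call(generate_scenario, manifest)

#' @export
print.mrp_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d taxa, %d sources (%d trees, %d plots), seed %d\n",
              length(x$true_tree$tip.label), length(x$sources),
              sum(vapply(x$sources, `[[`, "", "kind") == "tree"),
              sum(vapply(x$sources, `[[`, "", "kind") == "admixture"),
              x$manifest$seed))
  if (length(x$planted_rogues))
    cat("  planted rogues:", paste(x$planted_rogues, collapse = ", "), "\n")
  invisible(x)
}

#' Write a scenario to a directory of plain-text files
#'
#' Newick per source tree, TSV per Q-matrix, TSV classification and a JSON
#' manifest; [read_scenario()] restores the scenario from such a directory.
#'
#' @param scenario an `mrp_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (src in scenario$sources) {
    if (src$kind == "tree") {
      f <- paste0(src$source_id, ".nwk")
      write_newick(src$payload, file.path(dir, f))
    } else {
      f <- paste0(src$source_id, ".tsv")
      write_qmatrix(src$payload, file.path(dir, f))
    }
    meta[[src$source_id]] <- list(file = f, kind = src$kind,
                                  partition = src$partition,
                                  rooted = src$rooted,
                                  has_hominin_outgroup = src$has_hominin_outgroup)
  }
  write.table(scenario$classification$table,
              file.path(dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(scenario$true_tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(list(sources = meta,
                            manifest = scenario$manifest,
                            planted_rogues = scenario$planted_rogues,
                            planted_admixed = scenario$planted_admixed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#' @param dir directory path.
#' @return An `mrp_scenario`.
#' @export
read_scenario <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sources <- lapply(names(man$sources), function(id) {
    s <- man$sources[[id]]
    payload <- if (s$kind == "tree")
      read_newick(file = file.path(dir, s$file),
                  rooted_hint = isTRUE(s$rooted))
    else read_qmatrix(file.path(dir, s$file))
    source_record(id, s$kind, s$partition, payload,
                  rooted = if (s$kind == "tree") isTRUE(s$rooted) else NA,
                  has_hominin_outgroup = isTRUE(s$has_hominin_outgroup))
  })
  names(sources) <- names(man$sources)
  cls <- read.table(file.path(dir, "classification.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE, quote = "")
  true_tree <- read_newick(file = file.path(dir, "true_tree.nwk"))
  structure(list(true_tree = true_tree, sources = sources,
                 classification = classification_matrix(cls),
                 planted_rogues = unlist(man$planted_rogues),
                 planted_admixed = unlist(man$planted_admixed),
                 manifest = lapply(man$manifest, function(x) x)),
            class = "mrp_scenario")
}
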