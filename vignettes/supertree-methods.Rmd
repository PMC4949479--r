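---
title: "Supertree synthesis of population trees and admixture plots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supertree synthesis of population trees and admixture plots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpsupertree)
```

## The problem

Published phylogenies of human populations come from many incommensurable
data types: genome-wide allele frequencies, whole genomes, autosomal loci,
Y-chromosomal and mitochondrial markers, the HLA system, classical
polymorphisms, and lexical or structural features of languages. Individual
studies sample different, partially overlapping sets of populations, some
publish rooted trees and some unrooted ones, and a substantial body of
evidence comes not as trees at all but as admixture bar plots
(STRUCTURE/FRAPPE/ADMIXTURE Q-matrices). No single supermatrix analysis can
combine raw data of such different kinds; a supertree analysis can combine
their *topologies*.

`mrpsupertree` implements the matrix-representation-with-parsimony (MRP)
route to such a synthesis, together with the robustness machinery a careful
analysis of this kind needs: a weighting-by-rooting sensitivity grid,
wildcard (rogue) taxon detection with pruned consensus, tree-comparison
statistics, and consistency/retention-index tests of how well linguistic
classifications fit the genetic synthesis.

## Matrix representation with parsimony

Each source tree is converted to a partial matrix of additive binary
(Baum–Ragan) characters: one character per internal node (the root is
omitted, being constant, and trivial single-taxon clades are omitted
because neither can affect a parsimony search). Taxa descended from the
node are scored `1`, other taxa present in the source `0`, and taxa of the
analysis universe absent from the source `-` (inapplicable). Unrooted
sources are coded per nontrivial split with an arbitrary fixed polarity.
`?` (unknown) and `-` are kept distinct in storage but both behave as fully
missing in optimization, the standard parsimony convention.

An admixture plot is coded as one character per cluster: a population with
membership proportion at or above 10% of a cluster is scored present (`1`),
below that neglected (`0`). The 10% threshold is the method's published
convention; it is a plain parameter (`admixture_config()`). Ambiguous
sections of a plot can be handled two ways: the source publication's
within-population heterogeneity can be pre-coded as `?` in the input
Q-matrix, and an optional *borderline band* (closed–open interval around
the threshold, default off, `[threshold - 0.05, threshold + 0.05)` when
enabled) codes borderline proportions as `?`. The band default is off
because a crisp rule is reproducible while "borderline" is inherently a
judgment call; enabling the band is a sensitivity check, not a different
method.

The partial matrices are merged over the union of taxa (`merge_matrices()`;
absent taxa get `-`), and the merged matrix is analyzed by weighted maximum
parsimony. Rooting is expressed through a hypothetical all-zero outgroup
taxon (`ALL0`): characters from sources treated as rooted score `ALL0 = 0`,
all others `ALL0 = ?`. Scoring unrooted-source characters as `?` rather
than `0` lets them constrain grouping without asserting polarity; the
published description of the method does not state which convention it
used, and `?` is the conservative standard choice.

## The parsimony engine

Characters are binary with missing data, so weighted Fitch parsimony is the
scoring model: the score of a tree is the sum over characters of weight
times the minimal number of state changes. The engine (C++ via Rcpp, as is
usual for tree-search code in R packages) provides:

* `fitch_score()` — exact scoring of arbitrary, possibly multifurcating
  trees (polytomies hard) by dynamic programming;
* `exhaustive_search()` — complete enumeration of all `(2n-5)!!` unrooted
  binary topologies for up to 9 (configurable, hard cap 10) taxa. This is
  the oracle against which the heuristic is validated;
* `heuristic_search()` — random addition sequence (greedy stepwise
  insertion, ties broken by a seeded uniform draw), hill-climbing branch
  swapping (NNI, SPR or TBR; TBR default), and an optional parsimony
  ratchet. After the replicates, the pool of best trees is expanded with
  equal-score neighbors so that the returned MP set reflects alternative
  equally parsimonious placements (capped by `max_trees_retained`,
  default 1000; hitting the cap flags the result truncated).

The default of 100 addition replicates is a desk-scale setting chosen so a
full 16-cell sensitivity run stays interactive; published analyses of this
kind use 10,000 replicates, which is simply a larger value of the same
parameter. The plateau expansion explores the equal-score neighborhood of
the optima; it is not a complete enumeration of the MP set (only the
exhaustive oracle guarantees that), which is the main reason the heuristic
is validated against the oracle rather than trusted blindly.

A deliberate simplification relative to the large tree-search programs:
sectorial searches, tree fusing and driven searches are not implemented.
The evidence standard of the analysis is "most parsimonious trees", and at
the problem sizes this package targets the random-addition + swap (+
ratchet) strategy reaches the exhaustive optimum essentially always (the
acceptance suite requires at least 19/20 exact hits on random 8-taxon
matrices).

## The sensitivity grid

Analytic choices that the data cannot settle are explored as a Cartesian
grid of four weighting schemes × four rooting schemes, 16 parameter sets
labelled `1.A`–`4.D` (`build_parameter_grid()`):

* weighting — (1) all partitions equal; (2) trees upweighted 1000× over
  admixture plots; (3) genetic/genomic trees 1000× over language trees and
  plots; (4) genomic trees 1000× over everything else. The factor 1000 is
  the published convention; `deactivate = TRUE` replaces the low class's
  weight 1 by 0, the variant used to confirm that 1:1000 downweighting
  already suppresses a partition.
* rooting — (A) all rooted trees and all plots rooted by `ALL0`; (B) only
  rooted trees; (C) only rooted genetic/genomic trees; (D) only sources
  featuring great-ape or archaic-hominin outgroups.

Weights are integer multipliers in the Fitch score, which reproduces the
1:1000 ratio semantics exactly.

## Consensus, comparison, and wildcard taxa

MP trees are summarized as strict (clades in all trees), semistrict
(clades in some tree, contradicted by none, assembled greedily by
frequency, then size, then label order) and frequency-difference (clade
frequency strictly exceeds that of every incompatible rival) consensus
trees. Unrooted tree sets are handled through a common leaf-rooted
representation in which clades correspond to splits.

Supertrees from different grid cells are compared by SPR distance: exact
(breadth-first search over the SPR graph) up to 8 leaves, and a greedy
agreement-pruning upper bound above that (each pruned unit — a leaf or a
shared pendant subtree — costs one regraft). The similarity percentage is
defined as `100 × (1 − d/(n−3))`; the normalization used by the
field's closed-source implementation is undocumented, so cross-study
similarity percentages should be read qualitatively. The anticonsensus of
two trees lists the clades of one that are incompatible with the other, in
both directions.

Wildcard (rogue) taxa are found by an iterative prune-and-measure greedy
procedure over candidates consisting of single taxa and cherries: the node
gain of a candidate is the resolution of the strict consensus of the
pruned trees minus the resolution of the unpruned consensus restricted to
the same reduced leaf set (this difference is provably nonnegative).
The maximum-gain candidate is pruned while the gain is at least
`min_gain` (ties broken lexicographically). A taxon whose removal gains
five or more nodes under some parameter set is recommended for exclusion
(`exclusion_threshold = 5`, the published rule). This is the observable
contract of iterative positional congruence reduction; the triplet-based
refinements of the published algorithm are not needed for node-gain-based
exclusion and pruned-consensus inspection, which is all the pipeline uses.

## Classification fit and linguistic constraints

A categorical classification (language families, macrofamilies) becomes one
binary character per family. Fit on a supertree is measured per family by
the consistency index `CI = m/s` and retention index `RI = (g−s)/(g−m)`,
with `m = 1`, `g` = the count of the rarer observed state, and `s` the
Fitch steps on the tree. Because a family of `N` populations can never
score below `CI_min = 1/N`, the report attaches `CI_min` and the excess
`CI − CI_min`, making fit comparable across families of different size.
Ensemble values are `ΣM/Σs` and `(Σg−Σs)/(Σg−Σm)` over informative
characters.

Constrained supertrees implement topological constraints exactly as the
MRP literature does for linguistic classifications: the family characters
are appended at weight 1000× (with the linguistic source partitions
upweighted alongside) and the whole matrix rooted by `ALL0`. Parsimony then
enforces every fully scored family as a clade unless a heavier character
conflicts; populations scored `?` (documented language-shift groups)
attach wherever the genetic signal puts them — including, legitimately,
inside a constrained family. Mutually incompatible constraint characters
trigger a warning naming the pair; the search proceeds and the heaviest
compatible set wins.

## Group status

Figure-style summaries classify a named group on each cell's consensus as
*monophyletic* (some node's leaf set equals the group), *paraphyletic or
unresolved* (gray), or *polyphyletic*. The gray category is formalized
here as: the group's membership split is compatible with every split of
the (possibly unresolved) topology — equivalently, the group is a clade
under some rooting of some resolution, i.e. it attains a single character
step. This formalization reproduces the intended verbal rule on its test
cases (a group that is the complement of a nested clade is gray; a group
scattered across incompatible splits is black) and is invariant to leaf
order and to pruning taxa outside the group's containing clade. Groups
that are "a clade minus several nested clades" but whose membership split
conflicts with the topology are classified black under this rule; the
verbal definitions in the systematics literature genuinely disagree on
such cases, and the split-compatibility rule was chosen because it is
deterministic, rerooting-consistent, and matches the published examples.

## The synthetic-data generator

The compiled datasets such analyses run on are not redistributable, so the
package ships a generator whose scenarios have known ground truth
(`generate_scenario()`):

* a Yule (uniform random-split) rooted binary true tree with leaves
  `P001...`;
* source trees drawn by restricting the truth to random taxon subsets
  (default 50% coverage), perturbing with NNI moves (default 1 — NNI count
  is the noise unit because the method is purely topological), and tagging
  with a data partition. The partition census mirrors the proportions of a
  typical compiled dataset (HLA and other genetic trees dominate, language
  trees are fewer, ~15% of sources are admixture plots), so the weighting
  schemes have realistic leverage. 70% of tree sources are presented
  rooted and 30% of rooted genetic sources carry hominin outgroups —
  values chosen once as plausible for a published corpus, since no census
  of rooted/outgrouped sources is available;
* admixture Q-matrices built by cutting the truth into K clades and
  drawing rows from a Dirichlet centered on the clade indicator
  (concentration `alpha`, default 100 ≈ crisp plots; `Inf` is the exact
  limit); planted admixed taxa get 50/50 two-cluster rows;
* planted rogue taxa reattached at random positions in every source
  containing them;
* a family classification assigned from tree cuts, with a configurable
  misfit fraction (gene–language discordance) and `?`-scored taxa.

A scenario's `manifest` regenerates it bit-identically. What the generator
does *not* emulate: reticulation (admixture is injected only through
Q-matrix rows, not through conflicting tree signal with a migration
model), non-independence among published sources, taxon-sampling bias
correlated with geography, and branch-length information (the method never
uses it). Passing tests on these scenarios therefore demonstrate
correctness of the machinery and recoverability under topological noise,
not robustness to every pathology of real compiled datasets.

## Numerical choices and problem sizes

* Stepwise addition and swap ties are broken by a seeded uniform draw;
  greedy consensus assembly and wildcard ties are broken
  deterministically (frequency, size, label order), so identical
  configuration and seed give byte-identical report bundles.
* Weight-0 characters are dropped before search (provably no effect on the
  optimum); all-missing characters are rejected at matrix construction.
* Degenerate inputs: trees with fewer than 3 leaves code to an empty
  matrix with a warning; searches need 4 taxa; pruning below 3 leaves is
  an error; Q-matrix rows that do not sum to 1 within `1e-6` are rejected,
  never silently renormalized.
* The test and acceptance workloads use 8–30-taxon scenarios with 8–40
  sources, 2–10 addition replicates and SPR swapping — sizes chosen so the
  whole validation runs interactively on one core while still exercising
  every stage end-to-end; all of them are plain parameters that scale to
  study-size analyses.

## Known limitations

* The MP-set plateau expansion can miss equally parsimonious trees more
  than one rearrangement away from a found optimum; exhaustive enumeration
  is available only at oracle sizes.
* Exact SPR distance is exponential and restricted to small leaf counts;
  the upper bound above that is not tight for distant tree pairs.
* Admixture coding operates at population level; per-individual
  heterogeneity must be pre-coded as `?` in the input Q-matrix.
* Purvis and sister-group MRP variants, irreversible coding, implied
  weighting, support resampling (bootstrap/jackknife), and Bayesian or
  likelihood supertrees are out of scope.
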