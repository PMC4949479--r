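Package: mrpsupertree
Title: Supertree Synthesis of Population Trees and Admixture Plots by Matrix
    Representation with Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite phylogenies (supertrees) of human population
    samples from heterogeneous published sources: phylogenetic trees from
    genetic, genomic and linguistic data together with admixture plots
    (STRUCTURE/ADMIXTURE-style Q-matrices). Sources are converted to additive
    binary (Baum-Ragan) characters, merged, polarized by a hypothetical all-0
    outgroup, and analyzed by weighted maximum parsimony with a built-in
    search engine (random addition sequence, NNI/SPR/TBR swapping, optional
    ratchet, and an exhaustive oracle for small problems). Includes a 4x4
    weighting-by-rooting sensitivity grid, wildcard (rogue) taxon detection
    with pruned strict consensus, strict/semistrict/frequency-difference
    consensus trees, SPR distance and anticonsensus comparisons,
    consistency/retention-index fit of categorical classifications, linguistic
    topological constraints via upweighted characters, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
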