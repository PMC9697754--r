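Package: capsidphylo
Title: Structure-Based Comparison and Phylogeny of Viral Capsid Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise and all-vs-all rigid-body superposition of C-alpha
    protein structures with iterative structure-based residue correspondence,
    per-residue and windowed RMSD divergence profiles, RMSD distance-matrix
    neighbor-joining phylogenies compared against sequence phylogenies with
    bootstrap support, modeled-segment and cleavage-motif accounting for
    capsid proteins, and a synthetic homolog-family generator that co-evolves
    coordinates and sequences along a known tree so the whole pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
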