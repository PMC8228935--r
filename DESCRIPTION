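Package: allomap
Title: Residue Interaction Networks and Ensemble Analysis for Mapping
    Intramolecular Communication in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for mapping allosteric
    communication in proteins from structures and conformational ensembles.
    Builds coarse-grained residue interaction networks with hydrogen-bond
    weights, computes degree, closeness and betweenness centralities with
    threshold-based hot-spot and state-difference reports, performs essential
    dynamics (backbone principal component analysis, cosine-content filtering,
    free-energy landscapes), evaluates stability observables (RMSD, RMSF,
    Shrake-Rupley solvent accessibility, geometric hydrogen-bond detection and
    occupancy), selects representative low-energy frames, and derives
    cross-correlation community networks. Includes a synthetic-structure and
    synthetic-ensemble generator with analytically known properties so the
    entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
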