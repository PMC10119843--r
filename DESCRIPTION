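Package: pdniche
Title: Trajectory-Weighted Regulon Activity, Ligand-Receptor and Spatial
    Niche Scoring for Developmental Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting proximal-distal patterning and stromal
    niches in time-course single-cell RNA-seq with matched spatial
    transcriptomics. Implements entropic optimal-transport coupling of
    adjacent developmental time points with ancestor trajectory scores and
    fate probabilities, AUC-style per-cell regulon activity and
    trajectory-weighted fate activity profiles, a permutation-null
    ligand-receptor interaction score, spot-level cell-type composition
    with Moran's I spatially variable gene selection and an
    epithelium-adjacency score, neighbor-spot constrained ligand-receptor
    scoring, and a cross-species transcription-factor conservation
    classifier. Ships a seeded synthetic-data generator emulating a
    multi-time-point embryonic lung atlas with a hexagonal-lattice spatial
    section, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
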