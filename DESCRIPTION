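Package: dockrescore
Title: Machine-Learned Pose Selection and Affinity Rescoring for Ensemble Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Docking-engine-agnostic rescoring of ensemble docking runs.
    Per-protein-structure support-vector regression models predict the RMSD of
    candidate ligand poses from scoring-function interaction terms and select
    the top pose across a conformer-by-structure candidate ensemble; a second
    descriptor-augmented support-vector regression predicts binding affinity
    (pKi) from the selected poses. Includes classical consensus-scoring
    baselines (rank-by-number, rank-by-rank, rank-by-vote), descriptor
    preprocessing with genetic-algorithm and recursive-feature-elimination
    selection, Kennard-Stone train/test splitting, a complete external
    validation battery (through-origin statistics, the rm2 family, Lin's
    concordance correlation, Golbraikh-Tropsha style criteria, Cooper
    statistics and Kubat's G-mean), and a seeded synthetic benchmark
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
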