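Package: pentamut
Title: Predicting Local Structural Change of Protein Backbone upon Point
    Mutation
Version: 0.1.0
Authors@R:
    person("Pentamut", "Developers", email = "pentamut@example.org",
           role = c("aut", "cre"))
Description: Builds labeled datasets of pentamer pairs (five-residue protein
    fragments identical except at the central residue) from PDB coordinate
    files, labels each pair as structurally neutral or non-neutral by the
    C-alpha RMSD after optimal rigid superposition (Kabsch), encodes
    sequence-derived global, local-window and wild-type/mutant difference
    features, selects features by forward search on cross-validated AUC,
    trains an L2-regularized logistic regression model, and evaluates
    predictions with class-specific accuracy/coverage, ROC/AUC and
    enrichment-by-threshold analyses. Includes a synthetic-fixture generator
    (toy backbones with controlled perturbation, planted-signal feature
    matrices) so the whole pipeline runs at desk scale without external
    predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
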