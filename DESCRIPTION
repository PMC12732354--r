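Package: siRNAstack
Title: Chemical-Composition-Aware Prediction of siRNA Knockdown Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Curation, featurization and modelling toolkit for chemically
    modified small interfering RNA (siRNA) knockdown experiments. Provides a
    modification registry mapping nucleotide chemical modifications to
    per-base SMILES, per-nucleotide property-matrix featurization of
    sense/antisense duplexes with zero-padding to a reference length,
    hybrid alignment with mismatch quantification and a linear melting
    temperature model, gene-sequence embedding through a pluggable provider
    contract, leakage-controlled feature selection, and a two-stage
    probability-enhanced stacked model in which out-of-fold class
    probabilities from binary and multiclass efficacy classifiers feed a
    final gradient-boosted regressor. Includes a seeded synthetic-data
    generator with planted effects for end-to-end validation, and
    leave-one-gene-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    xgboost,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
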