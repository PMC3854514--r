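Package: tmexpo
Title: Lipid Exposure and Rotational Angles of Transmembrane Helices
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue lipid exposure (relative accessible
    surface area, rASA) of transmembrane helices from 3-D coordinates by
    rolling a 2.0 Angstrom spherical probe over the van der Waals surface,
    derives each helix's observed rotational angle from its structure
    (principal axis, top-view projection, lipid-facing direction), predicts
    rASA and burial status from sequence-derived features with
    support-vector models, and infers rotational angles from the rASA
    moment on the helical wheel. Includes evaluation metrics for angular
    and accessibility prediction and a synthetic-fixture generator with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
biocViews: StructuralPrediction, Proteomics, MachineLearning
Config/testthat/edition: 3
RoxygenNote: 7.3.3
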