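Package: aliSmoke
Title: Cigarette-Smoke Response Analysis for Air-Liquid-Interface Airway Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cigarette-smoke exposure studies of small-airway
    epithelial cells differentiated at the air-liquid interface (ALI). Provides
    per-pixel ciliary beat-frequency mapping from high-speed video stacks,
    adjusted area-under-curve summaries of longitudinal endpoints (TEER, qPCR
    delta-Ct) with one-sided contrasts from a compound-symmetry repeated-measures
    model, per-transcript linear-model differential expression with
    Benjamini-Hochberg control, and cross-dataset signature transfer (per-transcript
    min-max normalization, UPGMA clustering, random-forest classification with
    correlation-ranked feature ablation, and direction-consistency overlap).
    Ships synthetic-data generators with known ground truth so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    pracma,
    randomForest,
    pROC,
    ape
Suggests:
    testthat (>= 3.0.0),
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
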