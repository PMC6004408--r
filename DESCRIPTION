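Package: moacascade
Title: Cascaded Random-Forest Prediction of Compound Functional Effects at Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based prediction of the functional effect (activation versus
    inhibition) of small molecules at G-protein-coupled receptors, nuclear hormone
    receptors, ion channels and transporters. Implements a single multi-label
    random-forest architecture and two cascaded binding-then-function architectures
    with Platt-calibrated stage-2 classifiers, together with the data-assembly rules
    (BioAssay Ontology label mapping, 10 uM activity thresholds, conflict removal,
    sphere-exclusion sampling of putative inactives, minimum-size filters),
    stratified cross-validation and temporal evaluation protocols, nearest-neighbor
    chemical-space analysis, and distance-based applicability-domain curves with
    AD-AUC. A seeded synthetic-universe generator reproduces the statistical
    structure of proprietary bioactivity collections so the whole pipeline is
    testable without them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    caret,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
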