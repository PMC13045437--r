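Package: uhsr
Title: Hierarchical Symbolic Regression for Chromatographic
    Structure-Property Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distills interpretable retention indices from thin-layer
    chromatography (TLC) measurements with modular neural networks whose
    sub-models are restricted to chemist-defined feature groups, then
    discovers concise governing equations linking those indices to the
    retardation factor (Rf) by genetic-programming symbolic regression
    with constant optimization and parsimony-based equation selection.
    Includes chemically-intuitive featurization of solutes (functional
    group counts from SMILES, benzene-ring counts, dipole moment) and
    binary mobile-phase compositions, executable reference equations, a
    seeded synthetic-data generator built on those equations, and an
    end-to-end pipeline with cross-validation, feature importance,
    value-flow tracing and solvent recommendation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
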