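Package: formuqbd
Title: Quality-by-Design Toolkit for Gastroretentive Formulation Development
Version: 0.1.0
Authors@R:
    person("QbD", "Toolkit Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An integrated Quality-by-Design (QbD) workflow for developing
    directly compressible, gastroretentive (floating) oral dosage forms.
    Implements SeDeM expert-system powder scoring with excipient-correction
    calculations, constrained I-optimal mixture designs with Scheffe
    polynomial response-surface models, Derringer-Suich multi-response
    desirability optimization, dissolution release-kinetics fitting
    (zero-order, first-order, Higuchi, Korsmeyer-Peppas, Hixson-Crowell)
    with release-mechanism classification and swelling/erosion metrics,
    Heckel compaction analysis with mean-yield-pressure estimation, and a
    compartmental-absorption-and-transit (CAT) pharmacokinetic simulator
    with two-compartment disposition, non-compartmental analysis, and
    model-validation metrics (fold error, percent prediction error,
    relative bioavailability). Seeded synthetic-data generators emulate
    every stage so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
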