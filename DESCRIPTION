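Package: synscreen
Title: Multi-Model Synergy Scoring for Drug Combination Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis engine for multi-dose, multi-drug, multi-sample
    combination screens. Scores drug-combination dose-response matrices
    against the Bliss independence, Loewe additivity, highest single agent
    (HSA) and zero interaction potency (ZIP) reference models, and combines
    Bliss, Loewe and HSA into a conservative consensus synergy score.
    Includes model-based outlier detection and replacement for combination
    matrices and single-agent dose-responses, concentration-weighted synergy
    scoring, MuSyC potency/efficacy decomposition, multi-sample summary
    exports (heatmap and waterfall tables), a synthetic-data generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
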