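Package: sevc
Title: Soft Ensemble Vote Classification of Chimeric Virus-Like Particle
    Solubility from Amino Acid Hydrophobicity Scales
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of chimeric virus-like particle
    (cVLP) solubility with a soft ensemble vote classifier: one-level
    decision trees (stumps) trained on whole-sequence hydrophobicity
    features, one per amino acid hydrophobicity scale, aggregated by
    averaging signed-probability votes.  Includes Monte Carlo
    cross-validation with embedded MCC-based feature selection, a
    hill-climbing optimizer of per-insertion-strategy vote offsets, a
    hill-climbing synthesizer/optimizer of amino acid hydrophobicity
    scales driven by false-negative/false-positive composition
    differences, a continuous-vote regression extension for ammonium
    sulfate precipitation concentrations, and a fully parameterized
    synthetic construct-grid generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
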