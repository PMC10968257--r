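Package: aedfuse
Title: Autoencoder Fusion of Perimetry and OCT for Glaucoma Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses longitudinal visual field (24-2 perimetry) and peripapillary
    retinal nerve fiber layer (RNFL) thickness measurements into clinically
    interpretable "AE-fused fields" with an autoencoder whose encoding is
    regularized towards the measured visual field. Includes a Bayesian
    linear-regression baseline that combines functional and structural
    progression rates, a sliding-window visual-field-progression evaluation
    pipeline (sensitivity, specificity, F1, exact Wilcoxon signed-rank
    comparisons), and a longitudinal synthetic-cohort simulator with
    structure-function coupling, an RNFL floor effect and visual-field
    artifacts, so the full method can be trained and benchmarked without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
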