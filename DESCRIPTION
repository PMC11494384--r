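Package: sirnadesign
Title: siRNA Efficacy Prediction and Design with Dual Sequence Encoders and
    Thermodynamic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts small interfering RNA (siRNA) knockdown efficacy from the
    guide (antisense) sequence and its 57-nucleotide target mRNA context, and
    designs ranked siRNA candidates against a target transcript. The predictor
    fuses three feature channels: RNA nearest-neighbor thermodynamics (duplex
    free energy, terminal asymmetry, nucleotide composition), per-position
    sequence embeddings (a pretrained RNA language-model adapter with a
    deterministic fallback), and two independent sequence encoders (2D
    convolution, max and average pooling, bidirectional LSTM, two-layer
    multi-head transformer encoder) whose flattened outputs are concatenated
    into a multilayer perceptron head. Includes dataset harmonization with
    Needleman-Wunsch redundancy filtering, stratified cross-validation,
    feature-set ablation, gradient saliency maps, immune-motif and toxic-seed
    screening, PITA-style site-accessibility off-target scoring, and a
    synthetic-data generator with a planted, recoverable efficacy rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pROC
Config/testthat/edition: 3
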