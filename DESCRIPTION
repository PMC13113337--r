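Package: ctgfuse
Title: Multimodal Cardiotocography Fusion for Intrapartum Fetal Risk Assessment
Version: 0.1.0
Authors@R:
    person("ctgfuse", "developers", email = "ctgfuse@example.org", role = c("aut", "cre"))
Description: Tools for binary fetal-status classification from intrapartum
    cardiotocography (CTG). Implements the full pipeline: synthetic CTG fixture
    generation, invalid-point detection (range, adjacent-jump and sliding-window
    3-sigma rules), linear interpolation and smoothing, Gramian Angular
    Difference Field (GADF) imaging of fetal heart rate, a patch-based
    channel-independent time-series transformer encoder, a residual-network
    image encoder, a maternal-metadata autoencoder, a token-level multimodal
    fusion transformer with a label-smoothing plus auxiliary-reconstruction
    objective, evaluation metrics (accuracy, sensitivity, specificity, quality
    index, F1, MCC, AUC, Brier score), stratified splitting and a seeded
    multi-run experiment harness. All neural components run on a small built-in
    reverse-mode automatic-differentiation engine so the package trains and
    evaluates on a single CPU without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
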