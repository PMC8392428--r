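Package: dfntensor
Title: Seizure Prediction from Dynamic Functional Brain Network Tensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dynamic functional brain networks from multichannel scalp
    EEG by windowed, significance-thresholded Pearson correlation, stacks them
    into third-order binary tensors, extracts features with a rank-selected
    CP (CANDECOMP/PARAFAC) decomposition whose channel factor matrices are
    fixed after a single reference fit, classifies pre-ictal versus
    inter-ictal states with a regularized extreme learning machine tuned by
    closed-form (PRESS) leave-one-out error, and converts per-window label
    streams into seizure alerts with a consecutive-detection alarm rule.
    Includes a synthetic multichannel EEG generator with band-limited latent
    sources and class-dependent, time-varying coupling, an EDF reader/writer,
    baseline binary graph metrics (degree, clustering coefficient), and the
    two evaluation protocols (stratified cross-validation and
    leave-one-segment-out alarm prediction with prediction time).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
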