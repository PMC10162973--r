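Package: invcnn
Title: Decoding Stimulus Inversion from Cortical EEG with Compact
    Convolutional Networks and Relevance Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven analysis of the face- and body-inversion effect in
    source-level EEG. Generates synthetic single-trial cortical activity over
    the 68 Desikan-Killiany regions of interest, reduces vertex-level bundles
    to per-region waveforms by first-principal-component extraction with a
    polarity rule, trains compact convolutional neural network decoders of
    upright versus inverted stimulus orientation under leave-one-subject-out
    cross-validation, explains their decisions with epsilon-rule layer-wise
    relevance propagation, selects the most discriminant regions by three
    Wilcoxon signed-rank criteria with Bonferroni correction, and
    characterizes the selected regions with event-related potentials and
    Morlet-wavelet event-related (de)synchronization maps tested by
    cluster-based permutation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
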