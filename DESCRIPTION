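Package: erpdecode
Title: Single- and Multi-Trial Decoding of EEG Responses to Phosphene-Like Visual Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the discriminability of EEG responses to
    phosphene-like visual stimuli (solid bright blobs on a dark background,
    as elicited by electrical stimulation of the visual pathway). Provides a
    grid-based stimulus registry and presentation scheduler, a synthetic
    multichannel EEG generator with class-dependent event-related potential
    (ERP) structure and 1/f background noise, a preprocessing chain
    (impedance-based and average-RMS outlier channel rejection, zero-phase
    Hamming-window FIR bandpass, epoching, baseline correction), class-wise
    ERP averaging with cluster-based permutation statistics, calibrated
    RBF-SVM single-trial decoding with fold-matched chance-level testing
    (random decoder, Wilcoxon, Bonferroni), multi-trial aggregation of
    calibrated class probabilities via a normalized geometric-mean rule, and
    sensitivity maps of the trained kernel machines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
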