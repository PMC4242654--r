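Package: rpdc
Title: Renormalized Partial Directed Coherence Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Directed (Granger-causal) connectivity analysis of multichannel
    EEG in the frequency domain via renormalized partial directed coherence
    (rPDC). Provides a vector-autoregressive (VAR) model fitter with stability
    and residual diagnostics, spectral and transfer-matrix computation, rPDC
    with its constant chi-square significance level, a sliding-window
    time-frequency pipeline (Hjorth local-average re-referencing, anti-aliased
    polyphase resampling, per-window normalization), band summaries for named
    directed channel pairs, state-epoch extraction, and a repeated-measures
    ANOVA stage with Bonferroni-corrected paired contrasts. Includes a
    synthetic-data module that simulates stable VAR processes with known
    oscillatory directed couplings, including four-state sedation sessions,
    so every stage is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
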