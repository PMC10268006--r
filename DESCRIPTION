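Package: revforecast
Title: Forecasting Endogenous Perceptual Reversals from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for EEG correlates of perceptual
    destabilization preceding endogenous reversals of ambiguous figures
    presented in the discontinuous onset paradigm. Provides a synthetic
    generator for the paradigm's behavioral and electrophysiological
    structure (percept sequences, button presses, 32-channel EEG with a
    configurable bilateral-parietal destabilization signature),
    preprocessing (band-pass filtering, mastoid re-referencing, ICA-based
    blink removal, peak-to-peak artifact rejection, baseline correction,
    response-validity labeling), global field power with pointwise group
    statistics and a data-driven temporal region of interest,
    per-participant single-trial decoding of upcoming-reversal versus
    stable trials with a four-fold protocol, bootstrap accuracy
    distributions compared by Kolmogorov-Smirnov separability, and
    electrode-subset ablation to rank scalp regions by their contribution
    to classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
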