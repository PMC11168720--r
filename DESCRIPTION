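Package: bhisdg
Title: Directional Brain-Heart Interplay Estimation for Epilepsy EEG/ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved estimation of directed functional coupling between
    scalp EEG band oscillations and heart-rate-variability (HRV) dynamics,
    built on a physiologically plausible synthetic-data-generation model: an
    integral pulse frequency modulation (IPFM) heartbeat generator whose LF/HF
    modulation amplitudes are driven by EEG band power (brain-to-heart), and an
    exogenous autoregressive model of EEG band amplitudes driven by HRV band
    power (heart-to-brain), both inverted by sliding-window least squares.
    Includes EDF reading and writing, FIR preprocessing, R-peak detection and
    RR artifact correction, Hilbert-envelope and smoothed pseudo-Wigner-Ville
    band-power estimation, paired Wilcoxon channel maps with spatial cluster
    permutation correction, topographic rendering, z-scored minute trends, and
    a forward simulator of coupled EEG/ECG sessions with known coupling for
    verification by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
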