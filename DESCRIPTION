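Package: specslope
Title: Scale-Free Spectral Exponent Estimation for Electrophysiological
    Recordings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the aperiodic (scale-free, 1/f^beta) exponent of
    neural power spectra. Provides colored-noise and hierarchical cohort
    simulators with known ground truth, zero-phase Butterworth band
    isolation with exact response compensation, Welch power spectral
    density estimation, weighted least-squares log-log power-law fitting
    with standard errors, region-level aggregation, and the cohort
    statistics used for region discrimination (one-way ANOVA, Tukey HSD,
    exponent-gamma-power correlation, exponent-age regression, and a
    filter/FFT parameter robustness sweep). Includes delimited-text and
    EDF input and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
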