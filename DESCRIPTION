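Package: nirswallow
Title: Event-Related fNIRS Analysis of Swallowing Across Head Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related functional
    near-infrared spectroscopy (fNIRS) studies of swallowing under different
    head postures (chin-down, chin-neutral, chin-up). Provides a forward
    generator for complete synthetic sessions (two-wavelength optical
    intensity, laryngeal accelerometry, respiratory plethysmography, and
    ground-truth swallow events under a blocked bolus-delivery protocol),
    swallow-onset detection from the rectified and Bartlett-smoothed
    accelerometer envelope gated by respiratory apnea, conversion of raw
    intensity to oxy-/deoxyhemoglobin concentration changes via the modified
    Beer-Lambert law with zero-phase Butterworth band-pass filtering,
    short-separation regression and correlation-based signal improvement
    (CBSI) motion correction, baseline-normalized median hemodynamic-response
    summaries by position, hemisphere and within-block timing, and
    backward-elimination linear mixed modeling with Tukey-adjusted pairwise
    position contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
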