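Package: ocubss
Title: Ocular Artifact Removal for Continuous-Reading MEG via Blind Source Separation
Version: 0.1.0
Authors@R:
    person("MEG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removal of saccade and blink artifacts from magnetoencephalography
    (MEG) recorded during naturalistic continuous reading. Implements two
    pipelines built on blind source separation: a two-stage pipeline that
    extracts saccades with Second-Order Blind Identification (SOBI, joint
    approximate diagonalization of lagged covariance matrices with EOG-driven
    lag selection) and blinks with negentropy-based fixed-point ICA (FastICA),
    and a one-stage pipeline using a simplified adaptive-mixture ICA (AMICA)
    with generalized-Gaussian source densities and optional multiple models.
    Includes automated artifact-component identification (time-series features,
    gradiometer-pair RMS topographies, leadfield-correlation localization on a
    volumetric grid), DICS frequency-domain beamformer evaluation of power
    reduction with a common rank-limited filter, parcel-level group statistics,
    and a synthetic reading-MEG generator with full ground truth (semiperiodic
    saccade ramps with return sweeps and regressions, blink pulses, dipolar
    ocular topographies from a spherical head model, oscillatory plus 1/f
    brain sources, planar-gradiometer sensor pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
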