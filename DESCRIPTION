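Package: ssvepTuning
Title: Visuocortical Tuning Analysis of Frequency-Tagged EEG During Fear Generalization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for steady-state visually evoked
    potential (ssVEP) studies of social fear generalization. Generates synthetic
    experiment schedules, subject covariates and 129-channel frequency-tagged EEG
    epochs with known ground-truth condition tuning; preprocesses epochs (zero-phase
    low-pass filtering, distribution-based artifact detection, spherical-spline
    channel interpolation, condition averaging); applies a regularized
    spherical-spline current source density transform; computes 12 Hz
    signal-to-noise ratios pooled over an occipital sensor cluster; and analyzes
    the resulting tables with random-intercept linear mixed models (Satterthwaite
    denominator degrees of freedom, simple contrasts, partial R-squared) and
    weighted-contrast Bayesian model comparison under Jeffreys-Zellner-Siow
    priors, including per-subject visuocortical tuning indices, a default Bayes
    factor for the Pearson correlation, and a bootstrap Bayes factor for
    cross-phase conditioning effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
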