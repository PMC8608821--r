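Package: imefatigue
Title: Isotonic Muscular Endurance Testing: Simulation, sEMG Features, and
    Power-Loss Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing isotonic muscular endurance (IME) tests in
    which repetitive concentric contractions against a constant load are
    performed to voluntary exhaustion while dynamometer mechanics (torque,
    angle, angular velocity) and surface electromyography (sEMG) are recorded.
    Provides a trial simulator with controllable fatigue structure
    (per-repetition power decay, spectral compression, amplitude growth, and a
    75% power termination rule), zero-phase Butterworth band-pass filtering and
    adjacent-averaging smoothing, concentric-phase segmentation from the
    angular-velocity bell, nine per-contraction sEMG parameters (MAV, RMS, MNF,
    MDF, Hilbert-transform instantaneous IMNF/IMDF on Haar-wavelet-denoised
    signals, and the Hudgins set ZC, SSC, WL), and mapping of percent power
    loss from percent sEMG changes by univariate and stepwise multiple linear
    regression and by a multilayer perceptron trained with
    Levenberg-Marquardt, scored by signal-to-noise ratio and
    actual-versus-estimated regression, with supporting statistics
    (coefficient-of-variation screening, paired t, repeated-measures ANOVA
    with Bonferroni post-hoc, Pearson correlation, and regression-line
    slope/intercept F tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
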