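Package: buzzforce
Title: Directional Force and Thorax Vibration Analysis of Bee Defensive Buzzing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for analysing synchronized multichannel force and laser
    Doppler vibrometry recordings of buzzing bees: zero-phase bandpass
    filtering, kinematic derivation (displacement and acceleration from
    thorax velocity), overlapping 1024-sample interval segmentation,
    RMS-based inclusion criteria, Hamming-windowed FFT dominant-frequency
    estimation, force-versus-kinematics linear models, mixed-model ANOVA for
    post-material and force-direction effects, and population summaries. A
    seeded synthetic buzz generator with known ground truth (pulse-train
    forcing, harmonic velocity content, non-stationary fundamental,
    reflectance-loss bursts, post resonance, transducer quantization) makes
    the whole chain verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
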