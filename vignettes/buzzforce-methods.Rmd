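---
title: "Methods: measuring directional forces and thorax vibrations of buzzing bees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring directional forces and thorax vibrations of buzzing bees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buzzforce)
```

## The measurement problem

Bees that buzz-pollinate bite a flower's anther and contract their indirect
flight muscles (IFMs) with the wings disengaged, shaking pollen out through
apical pores. The same wing-disengaged behavior appears as defensive
buzzing, which can be elicited on demand and measured on a rigid post: a
multi-axis force transducer under the post records the three force
components the bee transmits (mN), while a laser Doppler vibrometer aimed
at the thoracic scutum records the thorax deformation velocity (mm/s). All
four channels are sampled synchronously at 10 kHz. The x and z axes are
chosen to align with the dorsal–ventral and dorsal–longitudinal muscle
groups, so the force decomposition maps onto the insect's actuation plane.

`buzzforce` turns those raw channels into the quantities a biomechanist
reports: per-interval dominant buzz frequency, peak forces per axis, peak
displacement/velocity/acceleration of the thorax, force-versus-kinematics
regressions, post-material and force-direction tests, and population
summaries. Because raw recordings of this kind are rarely redistributable,
the package also ships a seeded synthetic generator with known ground
truth, so every stage of the chain is verified by parameter recovery rather
than by fixtures.

## The analysis chain

1. **Bandpass.** Every channel is filtered to 10–2000 Hz with a Butterworth
   design (4 poles per band edge) applied forward–backward. Zero-phase
   filtering matters because force and velocity peaks are later paired in
   time; a causal filter would shift them against each other. The 10 Hz
   edge removes transducer drift; 2000 Hz retains the force harmonics of
   interest while rejecting the optical-artifact band.
2. **Kinematics.** Displacement is the cumulative-trapezoid integral of the
   filtered velocity, passed once more through the analysis band to remove
   the integration constant and drift; acceleration is computed by spectral
   differentiation on the even (mirrored) extension of the record.
   Frequency-domain *integration* (division by jω) was rejected after
   measurement: on a finite, non-periodic record, spectral leakage near the
   10 Hz edge is amplified by 1/ω and biased a 133.5 Hz test sinusoid's
   displacement by ~7%, whereas trapezoid-plus-bandpass reproduces the
   closed form V/(2πf) to 0.05%. Differentiation has the opposite
   character — multiplication by jω suppresses the low-frequency leakage —
   so it stays spectral and is exact for band-limited content.
3. **Segmentation.** The record is cut into 1024-sample windows (102.4 ms)
   overlapping 50%, indexed from zero; trailing samples that do not fill a
   window are dropped. At 10 kHz the FFT bin width is 9.765625 Hz.
4. **Inclusion criteria.** An interval enters the tabulated data only if
   (a) the RMS of its filtered x-force strictly exceeds 10 mN — excluding
   quiescence, when the bee simply stops — and (b) the RMS of its
   *unfiltered* velocity restricted to 2.5–5 kHz is strictly below
   0.5 mm/s. Energy in that band cannot be thorax motion (the buzz and its
   harmonics live below ~1 kHz); it indicates a poor vibrometer return from
   a badly angled scutum. The band RMS is computed spectrally (Hann
   periodogram with Parseval scaling) rather than by filtering the window:
   a zero-phase IIR filter applied to an isolated 1024-sample window whose
   in-band content is ~90 mm/s produces edge transients of the same order
   as the 0.5 mm/s threshold itself, while the spectral definition is
   transient-free and equals the band-limited RMS exactly for tones and
   broadband noise.
5. **Dominant frequency.** Each interval's filtered velocity is Hamming
   windowed, transformed, and scaled by the window's coherent gain so a
   bin-centered sinusoid of amplitude A reads A. Local maxima above
   1 mm/s (single-sided, i.e. 2 mm/s peak-to-peak) are pruned
   largest-amplitude-first to enforce 20 Hz separation, with exact ties
   broken toward lower frequency. The dominant frequency is the largest
   surviving peak — the frequency carrying most of the vibrational
   energy — which for strongly pulsed buzzing is usually, but not
   necessarily, the fundamental. No zero padding is applied by default, so
   the resolution stays at one bin.
6. **Peaks.** Per interval, the reported peak of each force and kinematic
   channel is the maximum absolute value, making results invariant to
   channel sign conventions.

## Statistics

* **Force–kinematics regressions** are ordinary least squares of peak
  x-force on one kinematic amplitude, fit per bee and pooled ("total").
  Following the convention that subdividing improves time resolution, each
  QC-passing interval is split into four 256-sample blocks and peaks are
  recomputed per block. Because parent windows overlap 50%, interior blocks
  would enter twice; `subdivide_for_regression()` deduplicates by start
  sample so each block is one data point. Slope and intercept CIs use the
  t-distribution with n − 2 df. A caveat found during validation: the
  block series is serially correlated (amplitude varies slowly), so these
  iid-OLS intervals are mildly anticonservative — in seeded recovery
  experiments at ~620 points their effective coverage is ~92% rather than
  95%. Point estimates and Pearson's r are unaffected.
* **Mixed-model ANOVA** tests post-material and force-direction effects
  with the individual bee as a random intercept, fit by REML
  (`lmerTest`) and tested with Satterthwaite-denominator F-tests.
  Responses are natural-log transformed when a Shapiro–Wilk test rejects
  residual normality (recorded in the result); seeded null simulations in
  the test suite confirm the type-I error is calibrated at α = 0.05.
* **Population summaries** report mean, SD, Q1, Q3 of the seven quantities.
  The default aggregation computes each bee's mean first and summarizes
  across the n bee means, so individuals with many intervals do not
  dominate; a pooled mode (across all intervals) is provided because
  quartiles of ten bee means are a coarse statistic and either convention
  is defensible.

## The synthetic generator

`generate_buzz()` emulates the statistical structure the analysis assumes:

* **Velocity** is a sum of `n_harmonics` harmonics of a fundamental f0(t)
  that follows a mean-reverting AR(1) on a 50 ms grid (stationary SD
  `f0_sd_hz`, default 20.8 Hz, hard-bounded at ±3 SD). A plain reflected
  random walk was rejected because its stationary distribution is uniform
  on the reflection interval, inflating the SD ~1.7× beyond the intended
  within-individual spread. Harmonic phases are uniform per realization.
* **Forces** are raised-cosine pulse trains, one pulse per fundamental
  period with width fraction 0.2 — buzzing bees push on the post in short
  periodic pulses, not sinusoidally, which is what gives real force spectra
  their extensive integer-harmonic content. Amplitudes parameterize the
  AC-coupled (mean-removed) peak, which is what a 10 Hz high-passed
  measurement chain reports; the pulse height is scaled by 1/(1 − w/2)
  internally so the realized oscillatory peak equals the stated value.
* **Slow amplitude modulation** (independent AR(1) gains for velocity and
  force, relative SD 0.15) reproduces the large within-individual
  variability of real trials; **quiescence spans** zero the bee while
  sensor noise continues; **reflectance-loss bursts** add 2.5–5 kHz
  band-limited noise to the velocity channel; forces are **quantized** to
  the 3.125 mN transducer resolution after an optional second-order **post
  resonance** (715 Hz plastic, 1400 Hz carbon, damping ratio 0.02).
* **Ground truth** is computed from the noise-free signals with closed-form
  harmonic kinematics (displacement A/(2πkf0), acceleration 2πkf0·A per
  harmonic), independent of the pipeline's numerics, plus the mean-removed
  clean force peaks and the expected QC status per interval.

Default conditions are the measured population's: fundamental 133.5 Hz,
AC-peak forces 172.3/67.3/115.1 mN (x/z dominate y, the IFM plane), 10 kHz
sampling. The five velocity harmonic amplitudes (90, 12, 4, 1.5, 0.8 mm/s)
were calibrated once, before any testing, so realized peak velocity
(~99 mm/s) and acceleration (~94 m/s²) match the reported population
scale.

### What the generator does not emulate

* A stationary harmonic series at 133.5 Hz mathematically ties peak
  displacement to roughly V/(2πf) ≈ 117 µm for a 98 mm/s velocity peak;
  the measured population's 32 µm displacement alongside that velocity
  implies transient, non-harmonic content this generator does not produce.
  Synthetic displacement therefore overshoots the measured scale ~3.5×,
  and displacement checks are done against generator truth, not against
  the measured values.
* `generate_population()` leaves the post-resonance transfer off by
  default. Real bees did not excite the post resonance, but the idealized
  raised-cosine pulse has substantial energy at its 5th–6th harmonics
  (~715 Hz), which the lightly damped transfer would amplify ~25× —
  synthetic force peaks would then be dominated by post ringing in a way
  the measured force spectra were not. Enable `apply_post_model = TRUE`
  (or set `post_model` directly) to study transfer effects deliberately.
* Sensor imperfections are limited to white noise, quantization and the
  scheduled HF bursts; there is no 1/f drift, no cross-axis coupling, and
  no mechanical coupling between force and velocity channels beyond the
  optional linear `force_coupling` law.

Passing recovery tests therefore demonstrate that the pipeline measures
what the generator produces, under the generator's assumptions — they
quantify algorithmic correctness, not the fidelity of any particular real
recording setup.

## Numerical edges and degenerate inputs

* Zero-phase IIR filtering has start-up transients at the record ends; the
  first and last one or two intervals of a trial can carry a few percent
  extra error in derived kinematics. Trials of a few seconds make this
  negligible at the population level.
* Sample rates inferred from a time column must be uniform within 1 ppm;
  nothing is resampled.
* Records shorter than one window yield an empty interval list with a
  warning; an interval set in which nothing passes QC aborts the pipeline
  with a per-bee census of exclusion reasons, keeping partial outputs.
* A spectrum with no peak above threshold is a valid outcome and is
  reported as a missing dominant frequency, not an error.
* Exact QC threshold hits are exclusions: the force criterion requires
  strictly more than 10 mN RMS, the reflectance criterion strictly less
  than 0.5 mm/s.

## Validation problem sizes

The test suite validates end-to-end recovery on a 10-bee population of 4 s
trials (frequency and force means recovered within 5% of truth; observed
errors are below 1%), slope/intercept recovery of a known force–velocity
coupling (slope 1.00, intercept 65.1 mN, scatter set for r ≈ 0.5) over 50
seeded replicates of 4 bees × 4 s, and mixed-ANOVA calibration over 200
null replicates of a 10-bee, two-post design. These sizes are the
package's own choices balancing statistical resolution against test-suite
turnaround.
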