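---
title: "Quantifying intrapersonal head-bow coordination from motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrapersonal head-bow coordination from motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headbow)
```

## The problem

A string player's bow strokes are instrumental gestures: they produce the
sound and are locked to the rhythmic content of the score. Head movements
are ancillary gestures: they do not produce sound, but they express and
possibly regulate the performance. `headbow` quantifies how tightly, at
which delay, and at which rhythmic timescales a player's head movements
couple to their own bowing, from two inputs:

* marker trajectories — three head-cap markers and one bow-tip marker,
  3D positions in mm sampled at 100 Hz, with occlusion gaps allowed;
* a beat annotation — onset times of half-note *steps* (two beats each,
  roughly 500 ms at the up-tempo performances this workflow targets),
  with bar indices and a played/pause flag. Only the annotated playable
  passages are analyzed.

The experimental context is a within-subject comparison between two
visual-coupling conditions of an orchestra (players facing the conductor
versus facing the other violin section), with four players, two
conductors and three takes each — collapsed to a 4 blocks × 6 replicates
× 2 conditions design. The package reproduces that complete chain on
synthetic data with known ground truth, so every stage is testable
without access to recordings.

## Preprocessing

The fixed chain is: average the three cap markers (rigid offsets make the
mean the head centre, with measurement noise reduced by √3); fill
occlusion gaps *strictly shorter* than 50 ms by cubic interpolation per
coordinate (a 50-ms gap stays missing; edge gaps stay missing); compute
scalar speed as the Euclidean displacement between successive samples
times the rate (mm/s, left-aligned timestamps); then, per playable
passage, z-score the speed and apply a zero-phase (forward–backward)
second-order Butterworth band-pass between 0.5 and 12 Hz. The band
brackets the metrical frequencies of an up-tempo performance (whole notes
near 1 Hz to eighth notes near 8 Hz). Filtering is never applied across
pauses, and any missing run that survives interpolation excludes every
analysis window that touches it — the simplest defensible rule, costing
well under 1% of windows at realistic gap rates.

`preprocess_trial()` applies the whole chain and is the only entry point
the analysis stages use, so the order cannot be accidentally changed.

## Windowed lagged cross-correlation

`windowed_xcorr_take()` slides 1000-ms windows (about one bar) with 50%
overlap within each passage and computes, per window, the Pearson
correlation between head and bow speed at lags −60 to +60 ms in 10-ms
steps, correlating only the overlapping part of the two sub-segments.
The lag bound is half the duration of the fastest notes, so correlations
never pair movements belonging to different notes. The sign convention is
fixed throughout the package: **negative lag means the head leads the
bow**. Four take-level indices summarize coordination:

* `peak_r` — peak correlation across lags, averaged over windows on the
  Fisher-z scale and transformed back (coupling strength irrespective of
  delay);
* `mean_lag_ms` — mean lag of the per-window peaks (signed lead/lag);
* `mean_abs_lag_ms` — mean absolute peak lag (temporal tightness);
* `lag_sd_ms` — standard deviation of peak lags across windows
  (stability of the coordination pattern).

Ties in the peak search are broken toward the smallest absolute lag, then
toward the negative lag; both rules are exercised by tests. Peak values
are Fisher-averaged; the per-lag average function (for plotting) averages
z per lag and transforms back.

## Spatial dispersion and convex hull

Movement amplitude uses the raw (gap-filled, unfiltered) positions — the
z-scored, filtered speeds have no spatial meaning. Per 1-s window (same
grid as the cross-correlation), `spatial_take_summary()` reports the mean
Euclidean distance between all C(100, 2) pairs of visited positions (mm)
and the volume of the 3D convex hull of the window's positions (cm³).
The hull is computed by an incremental (beneath-beyond) algorithm
implemented in C++; degenerate windows (collinear or coplanar points,
e.g. a near-still head) return volume 0 rather than an error, because
near-stillness is legitimate data. Tests pin the implementation to
analytic solids (cube, tetrahedron), to isometry invariance and degree-3
homogeneity, and to an independent brute-force-facet + Monte-Carlo
rejection oracle within 2%.

## Tempo-adaptive spectral analysis

Tempo fluctuates within a take, so power is not compared at fixed
frequencies. Each passage is cut into non-overlapping 3-s windows (three
cycles of the slowest component near 1 Hz); the trailing remainder joins
the last window, so no data is discarded (window lengths 300–599
samples). Each window gets a single Hamming-tapered periodogram,
zero-padded to 512 points (bin width 100/512 ≈ 0.195 Hz); windows longer
than 512 samples are never truncated — the transform length grows
instead. The mean of the inter-beat intervals whose onsets fall in the
window (half-open convention) is inverted to give the local quarter-note
frequency, and the whole/half/eighth frequencies follow the exact octave
ladder. Power is read at the bin nearest each level's local frequency
(`metrical_power_take()`), labelled P1–P4 from whole to eighth notes.
Power is reported in linear density units; decibel conversion is
presentation only. `power_correlation()` then correlates two effectors'
window-by-window power series per level, quantifying whether head and
bow wax and wane together at that timescale.

## Relative-phase consistency

`phase_coupling_take()` band-passes each (zero-padded) 3-s window ±0.5 Hz
around each level's local frequency with a two-pass second-order
Butterworth, extracts instantaneous phases via the analytic signal
(FFT-based Hilbert transform), and takes the head–bow phase difference,
wrapped to (−π, π], with the same convention: negative relative phase
means the head precedes the bow. Phase samples over the zero-padded tail
are discarded — padding corrupts analytic-signal phase — and the
retained samples are pooled across all windows of the take (pooling
maximizes sample support; window-weighted averaging was the alternative
and is not used). Three circular statistics summarize each level:

* `VL` — vector length of the mean unit phasor (1 = perfectly consistent
  phase relation, ≈ 0 = uniform);
* `MA` — mean angle (the signed mean phase difference);
* `MAA` — arithmetic mean of the absolute wrapped difference, in [0, π];
  π/2 under circular uniformity. This is the only reading of a
  "direction-free mean phase difference" that is well defined on wrapped
  angles.

Note that VL measured end-to-end reflects both the player's phase
stability *and* estimation noise from the narrow-band filtering of short
windows; it therefore sits well below the concentration of the
underlying phase process. The tests treat end-to-end VL as a monotone
function of the generator's phase-noise concentration, and verify the
statistics themselves (VL, MA, MAA) against von Mises and uniform
samples where the sampling distribution is known.

## Group comparison

`compare_conditions()` runs, per measure, a Friedman-type rank test
generalized to replicated blocks: within each violinist (block) all
6 × 2 take values are jointly ranked (mid-ranks for ties), and the
condition rank sums form the statistic
χ² = (k−1)/k · Σⱼ (Sⱼ − E)² / V, with E the null expectation and V the
exact finite-population variance of a rank sum, which is where tie
correction enters. For one replicate this reduces *exactly* to the
classical Friedman statistic (verified against `stats::friedman.test`).

The χ² reference distribution is inaccurate for four jointly-ranked
blocks: its p deviates by up to ~0.03 from the exact permutation null.
The reported p-value for replicated designs is therefore the within-block
label-permutation Monte Carlo probability (10,000 draws, a deterministic
data-derived seed, implemented in C++); the χ² probability is kept
alongside as `p_chisq`. No multiple-comparison correction is applied
across measures, and the comparison table says so implicitly by
reporting raw p-values; an optional grouping column re-runs the
comparison within strata (e.g. per conductor).

## The synthetic-data generator

`generate_trial()` simulates one take of one player at 100 Hz; it is
first-class, tested code, not a fixture. Its defaults encode the study
conditions the analysis assumes:

* **Timing.** Half-note steps with mean inter-beat interval 263 ms
  (~228 bpm), lognormal multiplicative jitter targeting an IBI
  coefficient of variation of 0.062, plus a slow sinusoidal drift
  (default 2%, one cycle per take) with random phase. 110 steps ≈ 58 s.
* **Passages.** Four playable passages (steps 1–9, 14–21, 26–53,
  77–110, ~4.5–18 s) separated by pauses in which both effectors hold
  position; segments prescribe the note value (whole to eighth) at which
  the bow reverses.
* **Bow.** One stroke per note along the stroke axis with a sinusoidal
  stroke profile — the bow slows into each reversal and peaks
  mid-stroke — so the speed waveform is a rectified sine with its
  fundamental at the note rate, and every speed harmonic is
  cosine-anchored to the metrical grid. Identical strokes keep that
  anchoring consistent across note values; stroke length scales down
  for faster notes. A slow lateral/vertical wander at fixed non-metrical
  frequencies (0.31/0.43 Hz, random phase) keeps the bow's point cloud
  three-dimensional without adding systematic power at any analysis
  frequency.
* **Head.** A sum of components at the four metrical frequencies, each a
  phase-skewed cosine cos(θ + 1.1 sin θ) along a fixed 3D direction. The
  skew mimics the natural fast-nod/slow-return asymmetry and — the
  reason it matters analytically — concentrates the *speed* spectrum at
  the component frequency itself instead of the rectification harmonic
  at twice the frequency, which is what makes metrical components
  recoverable from speed spectra. At skew 1.1 the spurious second
  harmonic of the speed is negligible. Each component's phase is
  referenced (offset π) to the bow's stroke-speed fundamental so that a
  head–bow lag of zero means speed-pattern synchrony — the quantity the
  windowed cross-correlation measures; this reference was calibrated
  once on noiseless uniform-note trials and is fixed.
* **Lag and phase noise.** The whole head trajectory is evaluated on a
  time-shifted musical clock, so the signed `head_bow_lag` (negative =
  head leads) is exact at every tempo. Phase noise is von Mises with
  concentration κ, drawn once per whole note and linearly interpolated —
  a slow wander whose spectral footprint stays below the metrical
  frequencies (faster, per-step innovations would leak into the
  half-note band and corrupt the spectra).
* **Sway, markers, noise, gaps.** Sub-band postural sway
  (0.33/0.40/0.47 Hz, per-axis random phase) broadens the spatial extent
  without entering the 0.5–12 Hz analysis band; three cap markers are
  exact rigid offsets from the head centre; white positional noise of
  0.3 mm per marker coordinate matches optical motion capture; occlusion
  gaps (default ~3 per minute, 20–120 ms) are injected into the bow
  marker, straddling the 50-ms interpolation rule.

Two canned regimes mirror the measured phenomenology:
`norm_profile()` (facing the conductor) has a single large whole-note
component (30 mm), larger postural sway (16 mm), κ = 2 and a −5 ms lag;
`pert_profile()` (facing the other section) has smaller multiscale
components (12/7/5/3 mm), small sway (3 mm), κ = 4 and a −10 ms lag.
`generate_dataset()` assembles the 4 × 2 × 6 study with per-violinist
amplitude multipliers (0.8–1.4) and per-take tempo realizations, all
deterministic from one master seed.

```{r, eval = FALSE}
res <- run_pipeline(design = study_design(), seed = 1)
res$comparison[, c("measure", "chi2", "p", "mean_NORM", "mean_PERT")]
```

## What the synthetic data does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: metrical periodicities with condition-dependent power, a
controlled head–bow lead/lag, tunable phase stability, realistic timing
jitter and drift, pauses, and occlusions. Passing tests therefore show
that each stage measures what it claims on signals of that structure,
with correct conventions (signs, windows, bins, ranks) end to end. They
do not show that real head motion is a sum of skewed sinusoids, that
real phase noise is von Mises, or that real bowing has identical
strokes; no claim about real recordings follows from a green suite.
Conversely, every *qualitative* contrast built into the two regimes —
stronger and more stable coupling, smaller but multiscale head motion,
unchanged bowing — is recovered by the full pipeline with the replicated
Friedman test in well over 80% of master seeds.

## Numerical and scale choices

Problem sizes used by the test suite and the acceptance script are the
study's own: ~58-s takes at 100 Hz, 4 × 2 × 6 designs, 20-seed
ensembles for stochastic properties, 1,000 directly-drawn null matrices
for the type-I calibration of the rank test (the calibration concerns
the test, not the motion model, so simulating motion capture for it
would add nothing), and 10,000-draw permutation oracles. Fisher
z-transformation clips |r| at 1 − 10⁻¹²; zero-variance segments refuse
to z-score; windows with missing samples are dropped rather than
imputed; degenerate hulls return 0; levels with fewer than 10 phase
samples are flagged rather than summarized. All randomness flows from
explicit integer seeds, and fixed seeds give byte-identical trials,
analyses and output files.

## Known limitations

* The head model is phase-locked to the bow's metrical clock; it cannot
  express coupling that varies *within* a take (e.g. drift from
  entrainment to another player).
* A single `head_bow_lag` applies to all metrical levels; level-specific
  leads (reported in real data as larger at faster timescales) arise
  here only through the waveform geometry, not as an independent dial.
* End-to-end VL is attenuated by phase-estimation noise in 3-s windows;
  absolute VL values are comparable only within a fixed analysis
  configuration.
* The χ² p-value of the replicated rank test is kept for reference but
  should not be used for inference at these design sizes; the
  permutation p is the default for a reason.
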