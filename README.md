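# headbow

Intrapersonal head–bow coordination analysis for ensemble motion capture.

## What this package is for

When violinists play, the bow is the instrumental gesture and the head is
an ancillary one — it produces no sound, yet it moves rhythmically and may
help regulate timing. `headbow` quantifies how strongly, at what delay,
and at which rhythmic timescales a player's head movements couple to their
own bow strokes, from 3D marker trajectories (three head-cap markers and a
bow tip, 100 Hz, mm) and a half-note beat annotation of the performance.
It is built for within-subject condition comparisons in small ensembles —
the motivating design is 4 violinists × 2 visual-coupling conditions ×
6 takes — and ships a seed-deterministic synthetic motion generator with
known ground truth so the entire chain is testable without recordings.

## The measures

For each take, restricted to annotated playable passages:

* **Preprocessing** — cap-marker averaging, cubic interpolation of
  occlusion gaps shorter than 50 ms, scalar speed (mm/s), per-passage
  z-scoring, zero-phase 2nd-order Butterworth band-pass 0.5–12 Hz.
* **Windowed lagged cross-correlation** — Pearson *r* between head and
  bow speed in 1-s windows (50% overlap) at lags −60…+60 ms (10-ms grid;
  negative lag = head leads). Indices per take: peak *r* (Fisher-z
  averaged), mean peak lag, mean |lag|, and the SD of peak lags across
  windows.
* **Spatial dispersion** — per 1-s window, the mean pairwise Euclidean
  distance of visited positions (mm) and the 3D convex-hull volume (cm³,
  incremental hull in C++), on raw gap-filled positions.
* **Tempo-adaptive spectra** — one Hamming periodogram per 3-s window
  (zero-padded to 512 points, 0.195-Hz bins); power extracted at the bins
  matching the *locally measured* whole/half/quarter/eighth-note
  frequencies (P1–P4), derived from the inter-beat intervals inside each
  window; plus head–bow power correlations per level.
* **Relative phase** — ±0.5 Hz band-pass around each level's local
  frequency, analytic-signal phase, head–bow phase difference pooled over
  windows; vector length (VL), mean angle (MA) and mean absolute angle
  (MAA) per level.
* **Group statistics** — a Friedman-type rank test for replicated blocks
  (violinists as blocks, takes as replicates, jointly ranked within
  block, tie-corrected):
  χ² = (k−1)/k · Σⱼ (Sⱼ − E)² / V, reducing exactly to the classical
  Friedman statistic for one replicate. For replicated designs the
  p-value comes from the within-block label-permutation null (10,000
  deterministic draws) because the χ² approximation is off by up to
  ~0.03 at four blocks.

## Worked example

Simulate one take in the "perturbed" regime (small, multiscale head
motion tightly locked to the bow) and analyze it:

```r
library(headbow)

grid  <- generate_beat_grid(tempo_config(), seed = 1, default_passages())
tempo_summary(grid)
#> take length 58.3 s, mean IBI 265.0 ms (226.4 bpm), IBI CV 0.0521

trial <- generate_trial(pert_profile(), grid, seed = 2)
pre   <- preprocess_trial(trial)

windowed_xcorr_take(pre)$indices
#> head-bow coordination over 78 windows: peak r 0.549, mean lag -7.7 ms,
#> mean |lag| 13.8 ms, lag sd 19.6 ms

phase_coupling_take(pre)
#>     level        VL          MA       MAA n_samples
#> 1   whole 0.2008019  0.29905145 1.3194675      4199
#> 2    half 0.1885578  0.90607883 1.4202545      4199
#> 3 quarter 0.4369339 -0.01216857 0.9582113      4199
#> 4  eighth 0.7281315 -0.30306064 0.6807487      4199
```

The take lasts ~58 s at ~226 bpm with 5% tempo variability. Head and bow
speeds correlate at *r* ≈ 0.55 with the head leading by ~8 ms, and phase
locking strengthens toward the faster metrical levels (VL 0.73 at the
eighth-note level), with slightly negative mean angles — the head
precedes the bow — at the fast levels.

A full study — simulate 4 violinists × 2 conditions × 6 takes, analyze
every take, and compare conditions per measure:

```r
res <- run_pipeline(seed = 1)
tab <- res$comparison[res$comparison$measure %in%
  c("peak_r", "lag_sd_ms", "head_interdistance_mm", "head_hull_cm3",
    "bow_interdistance_mm", "head_power_P3", "VL_P1"),
  c("measure", "chi2", "p", "mean_NORM", "sd_NORM", "mean_PERT", "sd_PERT")]
tab[-1] <- lapply(tab[-1], signif, 3)
print(tab, row.names = FALSE)
#>               measure  chi2      p mean_NORM sd_NORM mean_PERT sd_PERT
#>                peak_r 33.20 0.0001    0.1990  0.0196     0.516  0.0203
#>             lag_sd_ms 33.20 0.0001   45.9000  2.8100    20.400  2.1900
#> head_interdistance_mm 33.20 0.0001   30.4000  6.5200    13.500  2.8100
#>         head_hull_cm3 13.60 0.0003    3.7600  2.7300     2.360  1.3300
#>  bow_interdistance_mm  1.26 0.2920   78.9000  0.6550    79.000  0.7850
#>                 VL_P1 22.30 0.0001    0.1550  0.0829     0.312  0.0765
#>         head_power_P3 33.20 0.0001    0.0672  0.0177     0.205  0.0387
```

Between the two regimes, head–bow coupling strengthens (peak *r* 0.20 →
0.52) and stabilizes (lag SD 46 → 20 ms), head motion shrinks (mean
inter-distance 30 → 14 mm) while gaining power at the faster metrical
levels (P3 power 0.067 → 0.205), and the bow is unchanged — the
qualitative signature the analysis is designed to detect.

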