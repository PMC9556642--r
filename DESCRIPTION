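Package: headbow
Title: Intrapersonal Head-Bow Coordination Analysis for Ensemble Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how a string player's ancillary head movements
    coordinate with instrumental bow strokes from 3D motion-capture marker
    trajectories and half-note beat annotations. Implements the full
    analysis chain (marker averaging, short-gap cubic interpolation, speed
    computation, per-passage z-scoring and zero-phase Butterworth
    filtering), windowed lagged cross-correlation coordination indices,
    spatial dispersion and 3D convex-hull amplitude descriptors,
    tempo-adaptive power spectral analysis at the metrical frequencies of
    the score, Hilbert relative-phase coupling statistics, and
    replicated-block Friedman condition comparisons, together with a
    seed-deterministic synthetic motion generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
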