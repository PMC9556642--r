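#' Tempo configuration for the synthetic beat grid
#'
#' Describes the timing regime of one take: the piece is segmented in
#' half-note steps, each step spanning two beats, so a mean inter-beat
#' interval (IBI) of 263 ms corresponds to steps of ~526 ms and a tempo of
#' ~228 bpm. Step-to-step variability is multiplicative lognormal jitter
#' targeting the requested coefficient of variation (CV) of the IBI series;
#' a slow sinusoidal tempo drift with random phase can be superposed.
#'
#' @param mean_ibi mean inter-beat interval, ms (> 0). Default 263 ms.
#' @param cv target coefficient of variation of the IBI series. Default 0.062.
#' @param drift_amplitude relative amplitude of a one-cycle-per-take
#'   sinusoidal tempo drift (fraction of `mean_ibi`). Default 0.02.
#' @param n_steps number of half-note steps in the take (>= 2). Default 110
#'   (55 bars of two steps each, ~58 s at the default tempo).
#' @return an object of class `tempo_config`.
#' @export
tempo_config <- function(mean_ibi = 263, cv = 0.062, drift_amplitude = 0.02,
                         n_steps = 110) {
  stop_if_not_finite(c(mean_ibi, cv, drift_amplitude, n_steps), "tempo_config values")
  stopifnot(mean_ibi > 0, cv >= 0, drift_amplitude >= 0, n_steps >= 2)
  structure(list(mean_ibi = mean_ibi, cv = cv,
                 drift_amplitude = drift_amplitude,
                 n_steps = as.integer(n_steps)),
            class = "tempo_config")
}

#' Condition profile for synthetic head and bow motion
#'
#' Encodes one experimental regime of head motion. The head-centre
#' trajectory is a sum of oscillatory components at the four metrical
#' frequencies of the score (whole, half, quarter, eighth notes), each with
#' its own amplitude; the bow oscillates along its stroke axis with
#' reversals locked to the locally prescribed note value. Head components
#' are phase-locked to the bow clock with a signed time offset
#' (`head_bow_lag`, negative = head leads) plus von Mises phase noise.
#'
#' Two canned regimes mirror the measured phenomenology:
#' `norm_profile()` is head motion dominated by a single component near the
#' whole-note (~1 Hz) frequency, as seen when players follow the conductor;
#' `pert_profile()` is smaller, multiscale head motion with components at
#' all four metrical frequencies (~1, 2, 4, 8 Hz).
#'
#' @param level_amplitudes named numeric of length 4
#'   (`whole`, `half`, `quarter`, `eighth`): head component amplitudes, mm.
#' @param bow_amplitude reference stroke length of the bow, mm.
#' @param head_bow_lag signed head-bow time offset, ms; negative means the
#'   head leads the bow. `|lag| <= 60`.
#' @param phase_noise_kappa von Mises concentration of the head phase noise
#'   (>= 0; larger = more tightly phase-locked).
#' @param noise_sd additive white positional noise per marker coordinate, mm.
#' @param sway_amplitude slow postural sway amplitude, mm (per axis;
#'   spectral content below 0.5 Hz, outside the analysis band). Faster,
#'   multiscale head regimes leave less room for slow drift, so the
#'   perturbed regime uses a smaller value.
#' @param amplitude_scale dimensionless multiplier on all head amplitudes
#'   (used for per-player variation).
#' @return an object of class `condition_profile`.
#' @export
condition_profile <- function(level_amplitudes = c(whole = 30, half = 0,
                                                   quarter = 0, eighth = 0),
                              bow_amplitude = 400, head_bow_lag = -5,
                              phase_noise_kappa = 2, noise_sd = 0.3,
                              sway_amplitude = 10, amplitude_scale = 1) {
  stopifnot(length(level_amplitudes) == 4,
            all(METRICAL_LEVELS %in% names(level_amplitudes)))
  level_amplitudes <- level_amplitudes[METRICAL_LEVELS]
  stop_if_not_finite(c(level_amplitudes, bow_amplitude, head_bow_lag,
                       noise_sd, sway_amplitude, amplitude_scale),
                     "condition_profile values")
  stopifnot(all(level_amplitudes >= 0), bow_amplitude >= 0,
            abs(head_bow_lag) <= 60, !is.na(phase_noise_kappa),
            phase_noise_kappa >= 0, noise_sd >= 0, sway_amplitude >= 0,
            amplitude_scale >= 0)
  structure(list(level_amplitudes = level_amplitudes,
                 bow_amplitude = bow_amplitude,
                 head_bow_lag = head_bow_lag,
                 phase_noise_kappa = phase_noise_kappa,
                 noise_sd = noise_sd, sway_amplitude = sway_amplitude,
                 amplitude_scale = amplitude_scale),
            class = "condition_profile")
}

#' @rdname condition_profile
#' @export
norm_profile <- function() {
  condition_profile(level_amplitudes = c(whole = 30, half = 0, quarter = 0,
                                         eighth = 0),
                    head_bow_lag = -5, phase_noise_kappa = 2, noise_sd = 0.3,
                    sway_amplitude = 16)
}

#' @rdname condition_profile
#' @export
pert_profile <- function() {
  condition_profile(level_amplitudes = c(whole = 12, half = 7, quarter = 5,
                                         eighth = 3),
                    head_bow_lag = -10, phase_noise_kappa = 4, noise_sd = 0.3,
                    sway_amplitude = 3)
}

#' Missing-data gap specification
#'
#' Occlusion gaps injected into the bow-marker trajectory (in real
#' recordings the bow marker is the one that gets masked). Gap lengths
#' straddle the 50-ms interpolation rule so both the fill and the drop
#' branch of preprocessing are exercised.
#'
#' @param gap_rate expected gaps per second of take.
#' @param gap_length_range `(min, max)` gap length, ms.
#' @return an object of class `gap_spec`.
#' @export
gap_spec <- function(gap_rate = 0.05, gap_length_range = c(20, 120)) {
  stopifnot(gap_rate >= 0, length(gap_length_range) == 2,
            gap_length_range[1] <= gap_length_range[2],
            gap_length_range[1] > 0)
  structure(list(gap_rate = gap_rate,
                 gap_length_range = gap_length_range),
            class = "gap_spec")
}

#' Playable passages of the score
#'
#' A passage set lists the contiguous runs of half-note steps during which
#' the player actually plays, split into segments with a prescribed note
#' value (the bow reverses direction once per note of that value). Steps
#' outside all passages are pauses: the player holds position.
#'
#' @param segments data.frame with columns `passage` (integer id),
#'   `first_step`, `last_step` (inclusive step indices) and `note`
#'   (one of `"whole"`, `"half"`, `"quarter"`, `"eighth"`).
#' @return an object of class `passage_set` (a data.frame).
#' @export
passage_set <- function(segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("passage", "first_step", "last_step", "note") %in%
                names(segments)))
  stopifnot(all(segments$note %in% METRICAL_LEVELS),
            all(segments$first_step <= segments$last_step))
  o <- order(segments$first_step)
  segments <- segments[o, , drop = FALSE]
  if (any(diff(segments$first_step) <= segments$last_step[-nrow(segments)] -
          segments$first_step[-nrow(segments)]) &&
      any(segments$first_step[-1] <= segments$last_step[-nrow(segments)]))
    stop("passage segments overlap", call. = FALSE)
  len <- segments$last_step - segments$first_step + 1
  if (any(abs(len / NOTE_STEPS[segments$note] -
              round(len / NOTE_STEPS[segments$note])) > 1e-9))
    stop("segment length (in steps) must be a whole number of notes",
         call. = FALSE)
  rownames(segments) <- NULL
  class(segments) <- c("passage_set", "data.frame")
  segments
}

#' Default four-passage layout
#'
#' Four playable passages separated by pauses, spanning a 55-bar take of
#' 110 half-note steps (bar b = steps 2b-1 and 2b): steps 1-9, 14-21,
#' 26-53 and 77-110, lasting roughly 4.5 to 18 s at the default tempo.
#' Note values mix whole to eighth notes so that the bow carries energy at
#' every metrical level over the take.
#'
#' @return a `passage_set`.
#' @export
default_passages <- function() {
  passage_set(data.frame(
    passage    = c(1L, 1L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
    first_step = c(1L, 5L, 14L, 26L, 34L, 46L, 77L, 91L, 101L),
    last_step  = c(4L, 9L, 21L, 33L, 45L, 53L, 90L, 100L, 110L),
    note       = c("whole", "half", "quarter", "half", "eighth", "quarter",
                   "eighth", "quarter", "eighth")))
}

#' Generate a half-note beat grid
#'
#' Step durations are `2 * mean_ibi` with mean-corrected lognormal
#' multiplicative jitter whose dispersion targets the requested IBI CV,
#' plus an optional one-cycle sinusoidal drift with random phase.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [tempo_config()].
#' @param seed integer RNG seed.
#' @param passages optional [passage_set()] used to set the `played` flag.
#' @return a `beat_grid`: data.frame with columns `step_index`, `onset_s`
#'   (strictly increasing, first onset at 0), `duration_s`, `bar`, `played`.
#' @export
generate_beat_grid <- function(cfg, seed, passages = NULL) {
  stopifnot(inherits(cfg, "tempo_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_steps
  base <- 2 * cfg$mean_ibi / 1000
  sdlog <- sqrt(log(1 + cfg$cv^2))
  dur <- base * exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  if (cfg$drift_amplitude > 0) {
    phi <- runif(1, 0, 2 * pi)
    centre <- cumsum(dur) - dur / 2
    dur <- dur * (1 + cfg$drift_amplitude * sin(2 * pi * centre / sum(dur) + phi))
  }
  onset <- c(0, cumsum(dur[-n]))
  step <- seq_len(n)
  played <- rep(TRUE, n)
  if (!is.null(passages)) {
    stopifnot(inherits(passages, "passage_set"))
    if (max(passages$last_step) > n)
      stop("passage references steps outside the beat grid", call. = FALSE)
    played <- rep(FALSE, n)
    for (i in seq_len(nrow(passages)))
      played[passages$first_step[i]:passages$last_step[i]] <- TRUE
  }
  grid <- data.frame(step_index = step, onset_s = onset, duration_s = dur,
                     bar = (step + 1L) %/% 2L, played = played)
  class(grid) <- c("beat_grid", "data.frame")
  grid
}

# Continuous musical position s(t), in half-note steps (0 at the first
# onset, i - 1 at onset i), linearly interpolated and extrapolated at the
# local step rate. The metrical phase at level L is 2*pi*s / NOTE_STEPS[L].
step_position_fun <- function(grid) {
  on <- grid$onset_s
  n <- length(on)
  last_dur <- grid$duration_s[n]
  function(tt) {
    s <- approx(on, seq_len(n) - 1, xout = tt, rule = 2)$y
    lo <- tt < on[1]
    hi <- tt > on[n]
    s[lo] <- (tt[lo] - on[1]) / grid$duration_s[1]
    s[hi] <- (n - 1) + (tt[hi] - on[n]) / last_dur
    s
  }
}

# head oscillation waveform: phase-skewed cosine. The skew (fast one way,
# slow return, as in natural head nods) puts speed power at the component
# frequency itself rather than only at its rectification harmonic; at
# beta = 1.1 the spurious second harmonic of the speed is negligible.
head_wave <- function(theta, beta = 1.1) cos(theta + beta * sin(theta))

# fixed unit directions of the four head components (x right, y forward,
# z up); slow sway is mostly horizontal, fast nods mostly vertical.
HEAD_DIRS <- local({
  m <- rbind(whole   = c(0.77, 0.00, 0.64),
             half    = c(0.00, 0.92, 0.38),
             quarter = c(0.64, 0.64, 0.42),
             eighth  = c(0.00, 0.38, 0.92))
  m / sqrt(rowSums(m^2))
})

# slow postural sway: sub-band (< 0.5 Hz) sinusoids per axis with random
# phase; they broaden the spatial extent of head motion (dispersion, hull)
# without entering the 0.5-12 Hz analysis band
SWAY_FREQS <- c(0.33, 0.40, 0.47)

# rigid offsets of the three cap markers from the head centre, mm
HEAD_MARKER_OFFSETS <- list(c(0, -55, 45), c(-50, 40, 25), c(50, 40, 25))

# relative stroke length per note value (shorter notes use less bow)
STROKE_FRAC <- c(whole = 1, half = 0.75, quarter = 0.5, eighth = 0.3)

# Per-level phase reference of the head components relative to the musical
# clock, chosen so that at head_bow_lag = 0 the fundamental of the head
# SPEED waveform is phase-aligned, on average over the default passage
# layout, with the bow stroke-speed pattern at the same metrical frequency
# (zero lag = speed-pattern synchrony). Calibrated once on the noiseless
# generator; see the methods vignette.
HEAD_PHASE_REF <- c(whole = pi, half = pi, quarter = pi, eighth = pi)

# map each half-note step to its passage-segment row (NA during pauses)
step_segment_map <- function(passages, n_steps) {
  seg <- rep(NA_integer_, n_steps)
  for (i in seq_len(nrow(passages)))
    seg[passages$first_step[i]:passages$last_step[i]] <- i
  seg
}

#' Generate one synthetic take
#'
#' Simulates the marker trajectories of one player for one take at 100 Hz:
#' a bow marker oscillating along the stroke axis with constant-speed
#' strokes reversing at every note boundary (with a slight down/up-bow speed
#' asymmetry and slow lateral/vertical wander), and three rigid head-cap
#' markers around a head centre that is a sum of phase-skewed oscillations
#' at the metrical frequencies, phase-locked to the bow clock with the
#' profile's signed lag and per-step von Mises phase noise. During pauses
#' both effectors hold position. White positional noise is added per marker
#' and occlusion gaps are injected into the bow trajectory.
#'
#' @param profile a [condition_profile()].
#' @param grid a `beat_grid` from [generate_beat_grid()].
#' @param passages a [passage_set()]; must lie within the grid.
#' @param gaps a [gap_spec()].
#' @param seed integer RNG seed; identical inputs give byte-identical trials.
#' @return an object of class `synthetic_trial`: list with `time_s`,
#'   `head_markers` (list of three n x 3 matrices, mm), `bow` (n x 3 matrix,
#'   mm, `NA` rows where occluded), `beat_grid`, `passages`, `rate` (Hz) and
#'   `ground_truth` (the profile, realized IBIs, lag and seeds).
#' @export
generate_trial <- function(profile, grid, passages = default_passages(),
                           gaps = gap_spec(), seed = 1L) {
  stopifnot(inherits(profile, "condition_profile"),
            inherits(grid, "beat_grid"), inherits(passages, "passage_set"),
            inherits(gaps, "gap_spec"))
  n_steps <- nrow(grid)
  if (max(passages$last_step) > n_steps)
    stop("passage references steps outside the beat grid", call. = FALSE)
  set.seed(as.integer(seed))
  rate <- 100
  t_end <- grid$onset_s[n_steps] + grid$duration_s[n_steps]
  n <- floor(t_end * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  s_of <- step_position_fun(grid)
  s <- s_of(t)
  step_of_sample <- pmin(pmax(floor(s) + 1L, 1L), n_steps)
  seg_map <- step_segment_map(passages, n_steps)
  seg_of_sample <- seg_map[step_of_sample]
  played_sample <- !is.na(seg_of_sample)

  ## ---- bow: one stroke per note, reversing at note boundaries ---------
  # sinusoidal stroke profile: the bow slows into each reversal and peaks
  # mid-stroke, so the speed waveform is a rectified sine with fundamental
  # at the note rate, phase-anchored to the metrical grid (dips at note
  # boundaries). Identical strokes keep that anchoring consistent across
  # note values.
  bow_x <- numeric(n)
  for (i in seq_len(nrow(passages))) {
    idx <- which(seg_of_sample == i)
    if (!length(idx)) next
    note <- passages$note[i]
    ns <- NOTE_STEPS[[note]]
    u <- (s[idx] - (passages$first_step[i] - 1)) / ns
    note_i <- floor(u)
    dir <- 1 - 2 * (note_i %% 2)
    stroke_len <- profile$bow_amplitude * STROKE_FRAC[[note]]
    bow_x[idx] <- -dir * (stroke_len / 2) * cos(pi * (u - note_i))
  }
  bow_x <- freeze_pauses(bow_x, played_sample)
  # slow lateral/vertical wander (string changes, bow angle) at fixed
  # non-metrical frequencies with random phase, so it adds no systematic
  # content at the analysis frequencies
  phi_yz <- runif(2, 0, 2 * pi)
  bow_y <- 0.08 * profile$bow_amplitude * cos(2 * pi * 0.31 * t + phi_yz[1])
  bow_z <- 0.03 * profile$bow_amplitude * cos(2 * pi * 0.43 * t + phi_yz[2])
  bow <- cbind(x = bow_x, y = freeze_pauses(bow_y, played_sample),
               z = freeze_pauses(bow_z, played_sample))

  ## ---- head centre ----------------------------------------------------
  lag_s <- profile$head_bow_lag / 1000
  s_lag <- s_of(t - lag_s)
  amps <- profile$level_amplitudes * profile$amplitude_scale
  centre <- matrix(0, n, 3)
  # phase noise: von Mises draws once per whole note (every other step),
  # linearly interpolated -- a slow wander of the head relative to the
  # musical clock whose spectral footprint stays well below the metrical
  # frequencies (step-rate innovations would leak into the P2 band)
  draw_t <- grid$onset_s[seq(1, n_steps, by = 2)]
  nu_draws <- matrix(0, length(draw_t), 4)
  for (l in seq_along(METRICAL_LEVELS)) {
    lev <- METRICAL_LEVELS[l]
    if (amps[[lev]] <= 0) next
    if (is.finite(profile$phase_noise_kappa)) {
      nu_draws[, l] <- rvonmises(length(draw_t), 0,
                                 profile$phase_noise_kappa)
      nu <- approx(draw_t, nu_draws[, l], xout = t, rule = 2)$y
    } else nu <- 0   # kappa = Inf: perfectly phase-locked
    theta <- 2 * pi * s_lag / NOTE_STEPS[[lev]] + nu + HEAD_PHASE_REF[[lev]]
    centre <- centre + amps[[lev]] * head_wave(theta) %o% HEAD_DIRS[lev, ]
  }
  sway_amp <- profile$sway_amplitude * profile$amplitude_scale
  for (ax in 1:3) {
    phs <- runif(3, 0, 2 * pi)
    centre[, ax] <- centre[, ax] + sway_amp *
      colSums(sin(outer(2 * pi * SWAY_FREQS, t) + phs)) / sqrt(3)
  }
  centre <- apply(centre, 2, freeze_pauses, played = played_sample)

  head_markers <- lapply(HEAD_MARKER_OFFSETS, function(o) {
    m <- sweep(centre, 2, o, "+") +
      matrix(rnorm(3 * n, sd = profile$noise_sd), n, 3)
    colnames(m) <- c("x", "y", "z")
    m
  })
  bow <- bow + matrix(rnorm(3 * n, sd = profile$noise_sd), n, 3)

  ## ---- occlusion gaps on the bow marker -------------------------------
  gap_idx <- draw_gaps(n, rate, gaps)
  if (length(gap_idx)) bow[gap_idx, ] <- NA_real_

  structure(list(
    time_s = t, head_markers = head_markers, bow = bow,
    beat_grid = grid, passages = passages, rate = rate,
    ground_truth = list(profile = profile, head_bow_lag_ms = profile$head_bow_lag,
                        ibi_ms = rep(grid$duration_s * 500, each = 2),
                        phase_noise = nu_draws, n_missing = length(gap_idx),
                        seed = as.integer(seed))),
    class = "synthetic_trial")
}

# hold the last played value through pause samples
freeze_pauses <- function(x, played) {
  idx <- cummax(ifelse(played, seq_along(x), 0L))
  idx[idx == 0L] <- which(played)[1] %||% 1L
  x[idx]
}

# non-overlapping, non-touching gap placement; returns missing sample indices
draw_gaps <- function(n, rate, gaps) {
  n_gaps <- floor(gaps$gap_rate * (n / rate) + 1e-9)
  if (n_gaps == 0) return(integer(0))
  len_ms <- runif(n_gaps, gaps$gap_length_range[1], gaps$gap_length_range[2])
  lens <- pmax(1L, as.integer(round(len_ms * rate / 1000)))
  taken <- rep(FALSE, n)
  out <- integer(0)
  for (l in lens) {
    for (try in 1:200) {
      st <- sample.int(n - l - 1L, 1) + 1L       # keep first/last sample present
      span <- max(1L, st - 1L):min(n, st + l)    # require a present neighbour
      if (!any(taken[span])) {
        taken[st:(st + l - 1L)] <- TRUE
        out <- c(out, st:(st + l - 1L))
        break
      }
    }
  }
  sort(out)
}

#' Study design for a synthetic dataset
#'
#' @param n_violinists number of players (blocks). Default 4.
#' @param takes_per_condition repeated takes per condition. Default 6
#'   (three takes with each of two conductors, collapsed).
#' @param profiles named list of [condition_profile()]s, one per condition.
#' @param amp_multipliers per-violinist multiplier on head amplitudes
#'   (individual movement ranges differ).
#' @param tempo a [tempo_config()].
#' @param passages a [passage_set()].
#' @param gaps a [gap_spec()].
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_violinists = 4, takes_per_condition = 6,
                         profiles = list(NORM = norm_profile(),
                                         PERT = pert_profile()),
                         amp_multipliers = c(0.8, 1.0, 1.2, 1.4),
                         tempo = tempo_config(), passages = default_passages(),
                         gaps = gap_spec()) {
  stopifnot(n_violinists >= 1, takes_per_condition >= 1,
            length(amp_multipliers) == n_violinists,
            length(names(profiles)) == length(profiles))
  structure(list(n_violinists = as.integer(n_violinists),
                 takes_per_condition = as.integer(takes_per_condition),
                 profiles = profiles, amp_multipliers = amp_multipliers,
                 tempo = tempo, passages = passages, gaps = gaps),
            class = "study_design")
}

#' Generate a full synthetic study
#'
#' One trial per violinist x condition x take, each with its own beat grid
#' (takes differ in realized tempo) and its own trial seed, all derived
#' deterministically from the master seed.
#'
#' @param design a [study_design()].
#' @param seed master integer seed.
#' @return list with `trials` (list of `synthetic_trial`) and `meta`
#'   (data.frame: `violinist`, `condition`, `take`, seeds used).
#' @export
generate_dataset <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  conds <- names(design$profiles)
  meta <- expand.grid(take = seq_len(design$takes_per_condition),
                      condition = conds,
                      violinist = seq_len(design$n_violinists),
                      stringsAsFactors = FALSE)[, c("violinist", "condition", "take")]
  n_tr <- nrow(meta)
  seeds <- matrix(sample.int(2^31 - 1, 2 * n_tr), ncol = 2)
  trials <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    grid <- generate_beat_grid(design$tempo, seeds[i, 1], design$passages)
    prof <- design$profiles[[meta$condition[i]]]
    prof$amplitude_scale <- prof$amplitude_scale *
      design$amp_multipliers[meta$violinist[i]]
    trials[[i]] <- generate_trial(prof, grid, design$passages, design$gaps,
                                  seeds[i, 2])
  }
  meta$grid_seed <- seeds[, 1]
  meta$trial_seed <- seeds[, 2]
  list(trials = trials, meta = meta, design = design, seed = as.integer(seed))
}
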