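test_that("zero-noise beat grid has exactly constant IBIs", {
  g <- generate_beat_grid(tempo_config(mean_ibi = 250, cv = 0,
                                       drift_amplitude = 0, n_steps = 20),
                          seed = 1)
  expect_equal(derive_ibis(g), rep(250, 38), ignore_attr = TRUE)
})

test_that("beat grid recovers the requested IBI coefficient of variation", {
  g <- generate_beat_grid(tempo_config(mean_ibi = 263, cv = 0.06,
                                       drift_amplitude = 0, n_steps = 110),
                          seed = 11)
  expect_lt(abs(tempo_summary(g)$cv - 0.06), 0.015)
  # over seeds, mean CV within 3 standard errors of the target
  cvs <- vapply(1:20, function(sd) {
    tempo_summary(generate_beat_grid(
      tempo_config(mean_ibi = 263, cv = 0.06, drift_amplitude = 0), sd))$cv
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.06), 3 * sd(cvs) / sqrt(length(cvs)))
})

test_that("beat grid and trial generation are seed-deterministic", {
  cfg <- tempo_config()
  expect_identical(generate_beat_grid(cfg, 5, default_passages()),
                   generate_beat_grid(cfg, 5, default_passages()))
  g <- quick_grid(3)
  t1 <- generate_trial(pert_profile(), g, seed = 7)
  t2 <- generate_trial(pert_profile(), g, seed = 7)
  expect_identical(t1, t2)
})

test_that("beat-grid onsets are strictly increasing and passages respected", {
  g <- quick_grid(4)
  expect_true(all(diff(g$onset_s) > 0))
  pass <- default_passages()
  in_pass <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(pass)))
    in_pass[pass$first_step[i]:pass$last_step[i]] <- TRUE
  expect_identical(g$played, in_pass)
  expect_error(generate_beat_grid(tempo_config(n_steps = 50), 1,
                                  default_passages()),
               "outside the beat grid")
})

test_that("noiseless head centre carries spectral peaks at the metrical frequencies", {
  prof <- condition_profile(c(whole = 10, half = 6, quarter = 5, eighth = 3),
                            phase_noise_kappa = Inf, noise_sd = 0,
                            sway_amplitude = 0)
  g <- generate_beat_grid(tempo_config(cv = 0, drift_amplitude = 0), 5,
                          default_passages())
  tr <- generate_trial(prof, g, gaps = gap_spec(gap_rate = 0), seed = 9)
  centre <- average_head_markers(tr$head_markers[[1]], tr$head_markers[[2]],
                                 tr$head_markers[[3]])
  ext <- headbow:::passage_extents(tr$beat_grid, tr$passages)
  idx <- ext$passage4["start"]:ext$passage4["end"]
  nfft <- 8192
  fr <- (0:(nfft / 2)) * 100 / nfft
  pow <- rowSums(vapply(1:3, function(ax) {
    x <- centre[idx, ax] - mean(centre[idx, ax])
    (Mod(fft(c(x, rep(0, nfft - length(x)))))^2)[seq_len(nfft / 2 + 1)]
  }, numeric(nfft / 2 + 1)))
  f_q <- 1000 / tempo_summary(g)$mean_ibi_ms
  for (f0 in c(f_q / 4, f_q / 2, f_q, 2 * f_q)) {
    b <- which.min(abs(fr - f0))
    loc <- which.max(pow[(b - 4):(b + 4)]) + b - 5
    expect_lte(abs(loc - b) * 100 / nfft, 100 / 512)  # within one PSD bin
  }
})

test_that("single-component regime produces a single dominant oscillation", {
  prof <- condition_profile(c(whole = 20, half = 0, quarter = 0, eighth = 0),
                            phase_noise_kappa = Inf, noise_sd = 0,
                            sway_amplitude = 0)
  g <- generate_beat_grid(tempo_config(cv = 0, drift_amplitude = 0), 6,
                          default_passages())
  tr <- generate_trial(prof, g, gaps = gap_spec(gap_rate = 0), seed = 2)
  pw <- metrical_power_take(preprocess_trial(tr), "head")
  levs <- c("whole", "half", "quarter", "eighth")
  m <- vapply(levs, function(l) mean(pw$power[pw$level == l]), numeric(1))
  expect_gt(m["whole"], 5 * max(m[c("half", "eighth")]))
})

test_that("ground truth records the injected head-bow lag", {
  g <- quick_grid(2)
  prof <- condition_profile(c(whole = 5, half = 8, quarter = 8, eighth = 5),
                            head_bow_lag = -30, phase_noise_kappa = 20,
                            noise_sd = 0.2)
  tr <- generate_trial(prof, g, seed = 3)
  expect_identical(tr$ground_truth$head_bow_lag_ms, -30)
  # and the noiseless-lag convention propagates: head leads -> negative lag
  ml <- windowed_xcorr_take(preprocess_trial(tr))$indices$mean_lag_ms
  expect_lt(ml, -15)
})

test_that("injected gap budget matches the gap specification exactly", {
  g <- quick_grid(8)
  gs <- gap_spec(gap_rate = 0.1, gap_length_range = c(30, 90))
  tr <- generate_trial(norm_profile(), g, default_passages(), gs, seed = 4)
  expect_identical(sum(is.na(tr$bow[, 1])), tr$ground_truth$n_missing)
  expect_gt(tr$ground_truth$n_missing, 0)
  # all three coordinates share the missing mask
  expect_identical(is.na(tr$bow[, 1]), is.na(tr$bow[, 3]))
})

test_that("default study design yields 4 x 2 x 6 = 48 trials, deterministically", {
  ds <- generate_dataset(study_design(), seed = 21)
  expect_length(ds$trials, 48)
  expect_identical(dim(table(ds$meta$violinist, ds$meta$condition)), c(4L, 2L))
  expect_true(all(table(ds$meta$violinist, ds$meta$condition) == 6))
  ds2 <- generate_dataset(study_design(), seed = 21)
  expect_identical(ds, ds2)
})

test_that("per-violinist amplitude multipliers order the realized head motion", {
  des <- study_design(takes_per_condition = 1,
                      profiles = list(NORM = norm_profile()),
                      amp_multipliers = c(0.8, 1.0, 1.2, 1.4))
  ds <- generate_dataset(des, seed = 5)
  # oscillation amplitude in the analysis band, per trial (excludes the
  # randomly-phased sub-band sway and the frozen pause segments)
  spread <- vapply(ds$trials, function(tr) {
    c1 <- average_head_markers(tr$head_markers[[1]], tr$head_markers[[2]],
                               tr$head_markers[[3]])
    ext <- headbow:::passage_extents(tr$beat_grid, tr$passages)
    idx <- ext$passage4["start"]:ext$passage4["end"]
    mean(apply(c1[idx, ], 2, function(x) sd(bandpass(x, 0.5, 12, 100))))
  }, numeric(1))
  expect_identical(order(spread), 1:4)
})

test_that("invalid configurations are rejected", {
  expect_error(tempo_config(mean_ibi = -1))
  expect_error(tempo_config(mean_ibi = NaN))
  expect_error(condition_profile(head_bow_lag = 80))
  expect_error(condition_profile(level_amplitudes = c(whole = -1, half = 0,
                                                      quarter = 0, eighth = 0)))
  expect_error(gap_spec(gap_length_range = c(50, 20)))
  expect_error(passage_set(data.frame(passage = 1, first_step = 1,
                                      last_step = 3, note = "whole")),
               "whole number of notes")
})
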