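test_that("narrow-band filter preserves the centre and rejects the octave", {
  t <- seq(0, 5.11, by = 0.01)
  for (f0 in c(2, 4)) {
    x <- sin(2 * pi * f0 * t)
    y <- metrical_bandpass(x, f0)
    mid <- 150:350
    expect_lt(abs(max(abs(y[mid])) - 1), 0.1)
    y2 <- metrical_bandpass(sin(2 * pi * 2 * f0 * t), f0)
    expect_lt(max(abs(y2[mid])), 0.2)              # > 80% attenuation
  }
  expect_equal(metrical_bandpass(rep(0, 512), 4), rep(0, 512))
  expect_error(metrical_bandpass(rnorm(512), 0.3), "invalid band")
  expect_error(metrical_bandpass(rnorm(512), 49.8), "invalid band")
})

test_that("instantaneous phase follows the analytic-signal definition", {
  t <- seq(0, 5.11, by = 0.01)
  ph <- instantaneous_phase(cos(2 * pi * 2 * t))
  peaks <- which(abs(t %% 0.5) < 1e-9)             # cosine maxima
  expect_lt(max(abs(ph[peaks[3:8]])), 0.05)
  # quadrature: sin lags cos by pi/2
  d <- wrap_angle(instantaneous_phase(cos(2 * pi * 2 * t)) -
                  instantaneous_phase(sin(2 * pi * 2 * t)))
  expect_equal(mean(d[100:400]), pi / 2, tolerance = 0.02)
  # unwrapped phase advances 2*pi*f per second
  ph4 <- instantaneous_phase(sin(2 * pi * 4 * t))
  adv <- sum(wrap_angle(diff(ph4[200:300])))
  expect_lt(abs(adv - 8 * pi) / (8 * pi), 0.02)
  expect_error(instantaneous_phase(rep(0, 100)), "all-zero")
})

test_that("relative phase: sign convention, wrapping, length check", {
  expect_equal(relative_phase(rep(1, 5), rep(1, 5)), rep(0, 5))
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(pi), pi)                  # interval is (-pi, pi]
  # bow delayed by dt on a common component -> constant -2*pi*f0*dt
  t <- seq(0, 5.11, by = 0.01)
  f0 <- 2; dt <- 0.05
  ph <- instantaneous_phase(sin(2 * pi * f0 * t))
  pb <- instantaneous_phase(sin(2 * pi * f0 * (t - dt)))
  rp <- relative_phase(ph, pb)[100:400]
  expect_equal(mean(rp), -2 * pi * f0 * dt, tolerance = 0.02)
  expect_error(relative_phase(1:3, 1:4), "length")
})

test_that("circular summary: constants, uniform null, rotation equivariance", {
  s0 <- circular_summary(rep(0, 100))
  expect_equal(c(s0$VL, s0$MA, s0$MAA), c(1, 0, 0))
  s1 <- circular_summary(rep(pi / 2, 100))
  expect_equal(c(s1$VL, s1$MA, s1$MAA), c(1, pi / 2, pi / 2))
  expect_equal(s1$MA, 1.571, tolerance = 1e-3)
  set.seed(9)
  u <- runif(1000, -pi, pi)
  su <- circular_summary(u)
  expect_lt(su$VL, 0.1)
  expect_lt(abs(su$MAA - pi / 2), 0.1)
  expect_true(circular_summary(rnorm(5))$flagged)
  # adding a constant rotates MA and preserves VL
  a <- rvonmises(500, 0.3, 4)
  sa <- circular_summary(a)
  sb <- circular_summary(wrap_angle(a + 1))
  expect_equal(sb$VL, sa$VL, tolerance = 1e-12)
  expect_equal(wrap_angle(sb$MA - sa$MA), 1, tolerance = 1e-9)
})

test_that("von Mises sampler matches its analytic resultant length", {
  set.seed(10)
  for (kappa in c(2, 10)) {
    s <- circular_summary(rvonmises(4000, 0.5, kappa))
    expect_lt(abs(s$VL - vm_mean_resultant(kappa)), 0.03)
    expect_lt(abs(wrap_angle(s$MA - 0.5)), 0.1)
  }
  expect_lt(circular_summary(rvonmises(2000, 0, 0))$VL, 0.07)
})

test_that("take-level VL decreases with synthetic phase-noise dispersion", {
  vls <- sapply(c(12, 3, 0.8), function(kappa) {
    mean(sapply(1:3, function(sd) {
      prof <- condition_profile(c(whole = 2, half = 4, quarter = 8,
                                  eighth = 5),
                                phase_noise_kappa = kappa, noise_sd = 0.2)
      g <- quick_grid(sd + 40)
      tr <- generate_trial(prof, g, seed = sd + 60)
      ph <- phase_coupling_take(preprocess_trial(tr))
      ph$VL[ph$level == "quarter"]
    }))
  })
  expect_true(all(diff(vls) < 0))
})

test_that("end-to-end mean angle recovers the injected lag direction", {
  # head leading by 20 ms must give a negative quarter-level mean angle of
  # about -2*pi*f3*0.02 ~ -0.48 rad
  mas <- sapply(1:4, function(sd) {
    prof <- condition_profile(c(whole = 2, half = 4, quarter = 8, eighth = 5),
                              head_bow_lag = -20, phase_noise_kappa = 15,
                              noise_sd = 0.2)
    g <- quick_grid(sd + 70)
    tr <- generate_trial(prof, g, seed = sd + 90)
    ph <- phase_coupling_take(preprocess_trial(tr))
    ph$MA[ph$level == "quarter"]
  })
  expect_true(all(mas < 0))
  expect_lt(abs(mean(mas) - (-2 * pi * 3.8 * 0.02)), 0.15)
})
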