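test_that("window sliding: 50% overlap, remainder discarded", {
  expect_equal(nrow(slide_windows(350)), 6)     # 3.5 s passage
  expect_equal(nrow(slide_windows(100)), 1)
  expect_equal(nrow(slide_windows(90)), 0)
  w <- slide_windows(350)
  expect_equal(w$start, seq(1, 251, by = 50))
  expect_true(all(w$end - w$start + 1 == 100))
})

test_that("identical series correlate perfectly at lag zero", {
  x <- rnorm(100)
  f <- lagged_correlation(x, x)
  expect_equal(f$r[f$lag_ms == 0], 1)
  expect_equal(peak_pick(f)$lag_ms, 0)
})

test_that("a constructed 30 ms shift pins the sign convention: head leads -> negative", {
  t <- seq(0, 2, by = 0.01)
  s <- sin(2 * pi * 4 * t)
  head <- s[31:130]
  bow <- s[28:127]                      # bow(t) = head(t - 30 ms)
  f <- lagged_correlation(head, bow)
  expect_equal(peak_pick(f)$lag_ms, -30)
})

test_that("white-noise windows give Fisher z mostly within the null band", {
  set.seed(12)
  exceed <- 0; total <- 0
  for (i in 1:40) {
    f <- lagged_correlation(rnorm(100), rnorm(100))
    n_eff <- 100 - abs(f$lag_ms) / 10
    exceed <- exceed + sum(abs(f$z) > 3 / sqrt(n_eff - 3))
    total <- total + nrow(f)
  }
  expect_lt(exceed / total, 0.05)
})

test_that("Fisher transform: values, clipping, round trip", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_equal(z1, 13.8, tolerance = 0.1)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_lt(max(abs(fisher_z_inv(fisher_z(r)) - r)), 1e-9)
})

test_that("peak picking breaks ties by smallest |lag| then negative lag", {
  lags <- seq(-60, 60, by = 10)
  flat <- data.frame(lag_ms = lags, r = rep(0.5, 13))
  expect_equal(peak_pick(flat)$lag_ms, 0)
  r <- rep(0, 13); r[lags == -20] <- 0.7; r[lags == 20] <- 0.7
  expect_equal(peak_pick(data.frame(lag_ms = lags, r = r))$lag_ms, -20)
  r2 <- rep(NA_real_, 13)
  expect_null(peak_pick(data.frame(lag_ms = lags, r = r2)))
  r3 <- dnorm(lags, -10, 15)
  expect_equal(peak_pick(data.frame(lag_ms = lags, r = r3))$lag_ms, -10)
})

test_that("take aggregation: Fisher-averaged peak r and lag statistics", {
  pk <- data.frame(peak_z = fisher_z(c(0.3, 0.5)), lag_ms = c(-10, 10))
  agg <- aggregate_take(pk)
  expect_equal(agg$peak_r, tanh((atanh(0.3) + atanh(0.5)) / 2))
  expect_equal(agg$peak_r, 0.4048, tolerance = 1e-3)
  pk2 <- data.frame(peak_z = rep(0.4, 3), lag_ms = c(-10, 0, 10))
  agg2 <- aggregate_take(pk2)
  expect_equal(agg2$mean_lag_ms, 0)
  expect_equal(agg2$mean_abs_lag_ms, 20 / 3)
  expect_equal(agg2$lag_sd_ms, 10)
  one <- aggregate_take(data.frame(peak_z = 0.2, lag_ms = -20))
  expect_true(is.na(one$lag_sd_ms))     # flagged with < 2 windows
})

test_that("swapping head and bow negates the peak lag and preserves peak r", {
  set.seed(5)
  t <- seq(0, 0.99, by = 0.01)
  for (i in 1:10) {
    shift <- sample(c(-3, -2, -1, 1, 2, 3), 1)
    x <- sin(2 * pi * 3 * seq(0, 2, by = 0.01) + runif(1, 0, 2 * pi)) +
      0.2 * rnorm(201)
    head <- x[51:150]
    bow <- x[(51 - shift):(150 - shift)]
    f1 <- peak_pick(lagged_correlation(head, bow))
    f2 <- peak_pick(lagged_correlation(bow, head))
    expect_equal(f1$lag_ms, -f2$lag_ms)
    expect_equal(f1$peak_r, f2$peak_r, tolerance = 1e-10)
  }
})

test_that("vectorized window correlation matches the single-window path", {
  set.seed(6)
  hm <- matrix(rnorm(500), 100, 5)
  bm <- matrix(rnorm(500), 100, 5)
  rmat <- headbow:::lagged_correlation_matrix(hm, bm)
  for (i in 1:5) {
    f <- lagged_correlation(hm[, i], bm[, i])
    expect_equal(rmat[, i], f$r, tolerance = 1e-12)
  }
})

test_that("windows containing missing samples are dropped from the take analysis", {
  g <- quick_grid(13)
  tr <- generate_trial(norm_profile(), g,
                       gaps = gap_spec(gap_rate = 0.2,
                                       gap_length_range = c(60, 110)),
                       seed = 14)
  xc <- windowed_xcorr_take(preprocess_trial(tr))
  tr0 <- generate_trial(norm_profile(), g, gaps = gap_spec(gap_rate = 0),
                        seed = 14)
  xc0 <- windowed_xcorr_take(preprocess_trial(tr0))
  expect_lt(xc$indices$n_windows, xc0$indices$n_windows)
})
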