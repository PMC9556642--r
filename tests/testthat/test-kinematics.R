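test_that("head-marker averaging is the coordinate-wise mean with NA propagation", {
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(average_head_markers(m, m, m), m)
  a <- matrix(rep(c(0, 0, 0), each = 5), 5, 3)
  b <- matrix(rep(c(3, 0, 0), each = 5), 5, 3)
  c3 <- matrix(rep(c(0, 3, 0), each = 5), 5, 3)
  expect_equal(average_head_markers(a, b, c3)[1, ], c(1, 1, 0))
  b[4, 2] <- NA
  expect_true(is.na(average_head_markers(a, b, c3)[4, 2]))
  expect_error(average_head_markers(a, b[1:4, ], c3), "identical dimensions")
})

test_that("gaps strictly shorter than 50 ms are filled cubically, longer kept missing", {
  x <- as.numeric(1:60)                      # linear in t
  m <- cbind(x, 2 * x, -x)
  m[11:13, ] <- NA                           # 3 samples = 30 ms
  m[30:35, ] <- NA                           # 6 samples = 60 ms
  f <- fill_short_gaps(m, rate = 100)
  expect_equal(f[11:13, 1], 11:13, tolerance = 1e-9)   # cubic reproduces linear
  expect_true(all(is.na(f[30:35, 1])))
  # boundary case: exactly 50 ms (5 samples) is NOT shorter than 50 ms
  m2 <- cbind(x)
  m2[20:24, 1] <- NA
  expect_true(all(is.na(fill_short_gaps(m2, rate = 100)[20:24, 1])))
  # edge gaps stay missing
  m3 <- cbind(x)
  m3[1:2, 1] <- NA
  expect_true(all(is.na(fill_short_gaps(m3, rate = 100)[1:2, 1])))
})

test_that("gap filling never alters present samples", {
  set.seed(33)
  m <- matrix(rnorm(300), 100, 3)
  miss <- sample(5:95, 8)
  m[miss, 1] <- NA
  f <- fill_short_gaps(m, rate = 100)
  expect_identical(f[-miss, ], m[-miss, ])
})

test_that("speed is displacement per sample times the rate, in mm/s", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(compute_speed(p, 100), c(100, 100))
  expect_equal(compute_speed(rbind(c(0, 0, 0), c(3, 4, 0)), 100), 500)
  expect_equal(compute_speed(matrix(1, 5, 3), 100), rep(0, 4))
  expect_error(compute_speed(matrix(1, 1, 3)), "at least 2")
  # missing endpoint -> missing speed; non-negativity
  p2 <- matrix(rnorm(60), 20, 3)
  p2[7, ] <- NA
  sp <- compute_speed(p2, 100)
  expect_true(all(is.na(sp[6:7])))
  expect_true(all(sp[!is.na(sp)] >= 0))
})

test_that("z-scoring standardizes present samples and rejects degenerate segments", {
  expect_equal(zscore_segment(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore_segment(rnorm(50, 5, 2))
  expect_equal(zscore_segment(z), z, tolerance = 1e-12)   # idempotent
  expect_error(zscore_segment(rep(4, 10)), "zero variance")
  expect_error(zscore_segment(c(1, NA)), "at least 2")
  x <- rnorm(30); x[5] <- NA
  expect_true(is.na(zscore_segment(x)[5]))
})

test_that("band-pass is zero-phase with the specified band edges", {
  t <- seq(0, 10, by = 0.01)
  inband <- sin(2 * pi * 4 * t)
  out <- bandpass(inband, 0.5, 12, 100)
  mid <- 300:700
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)      # passband gain ~ 1
  slow <- sin(2 * pi * 0.05 * t)
  expect_lt(max(abs(bandpass(slow, 0.5, 12, 100))), 0.1)  # >90% attenuation
  # zero phase: the impulse response is symmetric about the impulse
  imp <- rep(0, 4001); imp[2001] <- 1
  h <- bandpass(imp, 0.5, 12, 100)
  expect_equal(h[2001 + 1:500], h[2001 - 1:500], tolerance = 1e-9)
  # and time reversal commutes with filtering away from the edges
  x <- rnorm(4000)
  fr <- bandpass(rev(x), 0.5, 12, 100)
  rf <- rev(bandpass(x, 0.5, 12, 100))
  expect_equal(fr[1000:3000], rf[1000:3000], tolerance = 1e-6)
  expect_error(bandpass(c(x, NA)), "missing")
  expect_error(bandpass(rnorm(5)), "too short")
})

test_that("filtering is linear", {
  x <- rnorm(400); y <- rnorm(400)
  lhs <- bandpass(2 * x + 3 * y, 0.5, 12, 100)
  rhs <- 2 * bandpass(x, 0.5, 12, 100) + 3 * bandpass(y, 0.5, 12, 100)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("preprocessing runs the fixed chain and leaves long gaps missing", {
  g <- quick_grid(9)
  tr <- generate_trial(norm_profile(), g,
                       gaps = gap_spec(gap_rate = 0.15,
                                       gap_length_range = c(60, 120)),
                       seed = 10)
  pre <- preprocess_trial(tr)
  expect_s3_class(pre, "preprocessed_trial")
  sp <- unlist(lapply(headbow:::passage_list(pre), `[[`, "bow_speed"))
  expect_gt(sum(is.na(sp)), 0)          # long gaps survive into the speeds
  present <- sp[!is.na(sp)]
  expect_lt(abs(mean(present)), 0.5)    # z-scored per passage
})
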