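#' Non-overlapping 3-s spectral windows within a passage
#'
#' Consecutive non-overlapping windows of `window_s` seconds; the final
#' remainder shorter than one window is appended to the preceding window,
#' so window lengths range from `window_s * rate` to just under twice that.
#' A passage shorter than one window yields a single whole-passage window,
#' flagged via attribute `short`.
#'
#' @param n_samples passage length, samples.
#' @param rate sampling rate, Hz.
#' @param window_s window length, s (default 3: three cycles of the slowest
#'   metrical component near 1 Hz).
#' @return data.frame with columns `start`, `end`.
#' @export
segment_psd_windows <- function(n_samples, rate = 100, window_s = 3) {
  len <- round(window_s * rate)
  k <- n_samples %/% len
  if (k == 0) {
    out <- data.frame(start = 1L, end = n_samples)
    attr(out, "short") <- TRUE
    return(out)
  }
  start <- (seq_len(k) - 1L) * len + 1L
  end <- start + len - 1L
  end[k] <- n_samples                      # remainder joins the last window
  out <- data.frame(start = start, end = end)
  attr(out, "short") <- FALSE
  out
}

#' Power spectral density of one analysis window
#'
#' Single modified periodogram: Hamming taper over the actual samples,
#' zero-padding to `max(nfft, length(x))` points, one-sided density scaling
#' at the sampling rate. With `nfft = 512` at 100 Hz the bin width is
#' 100/512 ~ 0.195 Hz.
#'
#' @param x numeric window, no missing values, length >= 64.
#' @param rate sampling rate, Hz.
#' @param nfft minimum FFT length; windows longer than `nfft` are never
#'   truncated.
#' @return object of class `psd_window`: list with `freq` (Hz), `power`
#'   (density units), `nfft`, `n`.
#' @export
estimate_psd <- function(x, rate = 100, nfft = 512) {
  stop_if_not_finite(x, "PSD window samples")
  n <- length(x)
  if (n < 64) stop("PSD window shorter than 64 samples", call. = FALSE)
  nfft <- max(nfft, n)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xp <- c(x * w, rep(0, nfft - n))
  spec <- Mod(fft(xp))^2 / (rate * sum(w^2))
  half <- seq_len(nfft %/% 2 + 1L)
  power <- spec[half]
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[length(half)] <- 1
  structure(list(freq = (half - 1) * rate / nfft, power = power * scale2,
                 nfft = nfft, n = n),
            class = "psd_window")
}

#' Extract power at the tempo-matched metrical frequencies
#'
#' For each metrical level, the power at the frequency bin whose centre is
#' nearest the locally estimated target frequency.
#'
#' @param psd a `psd_window` from [estimate_psd()].
#' @param freqs a `metrical_freqs` (or named numeric, Hz) from
#'   [local_metrical_frequencies()]; targets must lie below the Nyquist.
#' @return data.frame with columns `level`, `target_hz`, `matched_hz`,
#'   `power`.
#' @export
extract_metrical_power <- function(psd, freqs) {
  f <- unclass(freqs)[METRICAL_LEVELS]
  if (any(f >= max(psd$freq)))
    stop("target frequency at or above Nyquist", call. = FALSE)
  df <- psd$freq[2] - psd$freq[1]
  bin <- pmin(pmax(round(f / df), 0), length(psd$freq) - 1L) + 1L
  data.frame(level = METRICAL_LEVELS, target_hz = as.numeric(f),
             matched_hz = psd$freq[bin], power = psd$power[bin],
             row.names = NULL)
}

#' Metrical power series of one take
#'
#' Segments every passage into non-overlapping 3-s windows, estimates one
#' PSD per window, and extracts power at the four metrical frequencies
#' locally matched to the tempo of that window (from the IBIs it contains).
#' Windows containing missing samples are dropped.
#'
#' @param pre a `preprocessed_trial`.
#' @param effector `"head"` or `"bow"`.
#' @param nfft minimum FFT length.
#' @return data.frame (one row per window x level): `passage`, `window`,
#'   `start_s`, `level`, `target_hz`, `matched_hz`, `power`.
#' @export
metrical_power_take <- function(pre, effector = c("head", "bow"),
                                nfft = 512) {
  effector <- match.arg(effector)
  rate <- pre$rate
  grid <- pre$beat_grid
  rows <- list()
  win_id <- 0L
  for (pn in names(passage_list(pre))) {
    p <- pre[[pn]]
    x <- if (effector == "head") p$head_speed else p$bow_speed
    w <- segment_psd_windows(length(x), rate)
    for (i in seq_len(nrow(w))) {
      seg <- x[w$start[i]:w$end[i]]
      if (anyNA(seg) || length(seg) < 64) next
      win_id <- win_id + 1L
      t0 <- p$start_s + (w$start[i] - 1) / rate
      t1 <- p$start_s + w$end[i] / rate
      freqs <- local_metrical_frequencies(grid, c(t0, t1))
      ext <- extract_metrical_power(estimate_psd(seg, rate, nfft), freqs)
      ext$passage <- pn; ext$window <- win_id; ext$start_s <- t0
      rows[[length(rows) + 1L]] <- ext
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[, c("passage", "window", "start_s", "level", "target_hz",
          "matched_hz", "power")]
}

#' Correlation of two metrical power series
#'
#' Pearson correlation, per metrical level, between two series of
#' window-wise power values (e.g. head vs bow of the same take): do the two
#' effectors wax and wane together at that timescale? Windows are paired by
#' the `window` id; levels with fewer than 3 paired windows or a constant
#' series give `NA`.
#'
#' @param a,b data.frames from [metrical_power_take()].
#' @return data.frame with columns `level`, `r`, `n`.
#' @export
power_correlation <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  out <- lapply(METRICAL_LEVELS, function(lev) {
    ai <- a[a$level == lev, ]
    bi <- b[b$level == lev, ]
    m <- merge(ai[, c("window", "power")], bi[, c("window", "power")],
               by = "window", suffixes = c("_a", "_b"))
    r <- if (nrow(m) < 3 || sd(m$power_a) == 0 || sd(m$power_b) == 0)
      NA_real_ else cor(m$power_a, m$power_b)
    data.frame(level = lev, r = r, n = nrow(m))
  })
  do.call(rbind, out)
}
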