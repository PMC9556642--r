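#' Narrow-band filter around a metrical frequency
#'
#' Two-pass (zero-phase) second-order Butterworth band-pass with edges
#' `f0 +/- halfwidth`; used to isolate one metrical component before phase
#' extraction.
#'
#' @param x numeric vector, no missing samples.
#' @param f0 centre frequency, Hz; `f0 - halfwidth` must be positive and
#'   `f0 + halfwidth` below Nyquist.
#' @param halfwidth half bandwidth, Hz. Default 0.5.
#' @param rate sampling rate, Hz.
#' @return filtered vector.
#' @export
metrical_bandpass <- function(x, f0, halfwidth = 0.5, rate = 100) {
  if (f0 - halfwidth <= 0 || f0 + halfwidth >= rate / 2)
    stop("invalid band: need 0 < f0 - halfwidth and f0 + halfwidth < Nyquist",
         call. = FALSE)
  bandpass(x, f0 - halfwidth, f0 + halfwidth, rate, order = 2)
}

# analytic signal via FFT (Marple): positive frequencies doubled,
# negative zeroed
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrow-band series
#'
#' Phase angle of the analytic signal (Hilbert transform); for a pure
#' sinusoid the unwrapped phase advances by `2*pi*f` per second over the
#' window interior.
#'
#' @param x narrow-band numeric vector.
#' @return phase series, radians in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x) {
  if (all(x == 0)) stop("phase undefined for an all-zero signal",
                        call. = FALSE)
  wrap_angle(Arg(analytic_signal(x)))
}

#' Head-bow relative phase
#'
#' Signed phase difference, wrapped to `(-pi, pi]`, with the convention
#' that NEGATIVE relative phase means the head precedes the bow: if the bow
#' is a delayed copy of the head on a common component at `f0`, the
#' relative phase is `-2*pi*f0*delay`.
#'
#' @param phase_head,phase_bow equal-length phase series, radians.
#' @return wrapped relative-phase series.
#' @export
relative_phase <- function(phase_head, phase_bow) {
  if (length(phase_head) != length(phase_bow))
    stop("phase series differ in length", call. = FALSE)
  wrap_angle(phase_bow - phase_head)
}

#' Circular summary of relative-phase samples
#'
#' The three coupling statistics of one take at one metrical level, over
#' all pooled instantaneous relative-phase samples: vector length
#' (VL, modulus of the mean unit phasor; 1 = perfect consistency), mean
#' angle (MA, argument of the mean phasor) and mean absolute angle (MAA,
#' arithmetic mean of `|angle|`, in `[0, pi]`; pi/2 under circular
#' uniformity).
#'
#' @param samples numeric vector of wrapped relative-phase angles, radians.
#' @param min_samples minimum sample support; fewer samples give a flagged
#'   all-`NA` result.
#' @return object of class `phase_summary`: list with `VL`, `MA`, `MAA`,
#'   `n`, `flagged`.
#' @export
circular_summary <- function(samples, min_samples = 10) {
  n <- length(samples)
  if (n < min_samples)
    return(structure(list(VL = NA_real_, MA = NA_real_, MAA = NA_real_,
                          n = n, flagged = TRUE), class = "phase_summary"))
  m <- mean(exp(1i * samples))
  structure(list(VL = Mod(m), MA = Arg(m), MAA = mean(abs(samples)),
                 n = n, flagged = FALSE),
            class = "phase_summary")
}

#' Multiscale phase-coupling analysis of one take
#'
#' For every 3-s spectral window and every metrical level: zero-pad the
#' window (as in the PSD analysis), band-pass `+/- halfwidth` around the
#' locally tempo-matched level frequency, extract instantaneous phases of
#' head and bow, and take their relative phase over the true data extent
#' only (phases over the zero-padded tail are discarded). Relative-phase
#' samples are pooled across all windows of the take before the circular
#' summary.
#'
#' @param pre a `preprocessed_trial`.
#' @param halfwidth half bandwidth, Hz.
#' @param nfft zero-padding target, samples.
#' @return data.frame with one row per level: `level`, `VL`, `MA`, `MAA`,
#'   `n_samples`.
#' @export
phase_coupling_take <- function(pre, halfwidth = 0.5, nfft = 512) {
  rate <- pre$rate
  grid <- pre$beat_grid
  pooled <- stats::setNames(vector("list", length(METRICAL_LEVELS)),
                            METRICAL_LEVELS)
  for (pn in names(passage_list(pre))) {
    p <- pre[[pn]]
    w <- segment_psd_windows(length(p$head_speed), rate)
    for (i in seq_len(nrow(w))) {
      idx <- w$start[i]:w$end[i]
      h <- p$head_speed[idx]; b <- p$bow_speed[idx]
      if (anyNA(h) || anyNA(b) || length(idx) < 64) next
      nlen <- length(idx)
      pad <- max(nfft - nlen, 0)
      hp <- c(h, rep(0, pad)); bp <- c(b, rep(0, pad))
      t0 <- p$start_s + (w$start[i] - 1) / rate
      freqs <- local_metrical_frequencies(grid, c(t0, t0 + nlen / rate))
      for (lev in METRICAL_LEVELS) {
        f0 <- freqs[[lev]]
        if (f0 - halfwidth <= 0 || f0 + halfwidth >= rate / 2) next
        ph <- instantaneous_phase(metrical_bandpass(hp, f0, halfwidth, rate))
        pb <- instantaneous_phase(metrical_bandpass(bp, f0, halfwidth, rate))
        rp <- relative_phase(ph[seq_len(nlen)], pb[seq_len(nlen)])
        pooled[[lev]] <- c(pooled[[lev]], rp)
      }
    }
  }
  out <- lapply(METRICAL_LEVELS, function(lev) {
    s <- circular_summary(pooled[[lev]] %||% numeric(0))
    data.frame(level = lev, VL = s$VL, MA = s$MA, MAA = s$MAA, n_samples = s$n)
  })
  do.call(rbind, out)
}
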