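#' Sliding 1-s window starts within a passage
#'
#' Windows of `length_ms` with fractional `overlap` slide within each
#' passage independently; the trailing remainder shorter than one window is
#' discarded. Windows containing any missing sample are dropped by the
#' callers.
#'
#' @param n_samples passage length in samples.
#' @param rate sampling rate, Hz.
#' @param length_ms window length, ms (default 1000, about one bar).
#' @param overlap fractional overlap between contiguous windows (default 0.5).
#' @return data.frame with columns `start`, `end` (sample indices, 1-based);
#'   zero rows if the passage is shorter than one window.
#' @export
slide_windows <- function(n_samples, rate = 100, length_ms = 1000,
                          overlap = 0.5) {
  len <- round(length_ms * rate / 1000)
  step <- round(len * (1 - overlap))
  stopifnot(len >= 2, step >= 1)
  if (n_samples < len)
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq(1L, n_samples - len + 1L, by = step)
  data.frame(start = starts, end = starts + len - 1L)
}

#' Fisher z-transformation and its inverse
#'
#' `fisher_z` is `atanh` with `|r|` clipped to `1 - 1e-12` so that r = +/-1
#' maps to a large finite value; `fisher_z_inv` is `tanh`. Correlations are
#' averaged on the z scale and transformed back for reporting.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param z Fisher z value(s).
#' @return transformed numeric vector.
#' @export
fisher_z <- function(r) atanh(pmax(pmin(r, 1 - 1e-12), -(1 - 1e-12)))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Lagged cross-correlation within one window
#'
#' Pearson correlation between the head and bow series of one analysis
#' window at each lag of the grid, correlating only the overlapping part
#' (both sub-segments re-centred within the overlap, which `cor` does).
#' Sign convention: a NEGATIVE lag means the head series is advanced
#' relative to the bow, i.e. the head leads; at lag l (samples), `head[i]`
#' is paired with `bow[i - l]`.
#'
#' @param head,bow numeric vectors of equal length, no missing samples.
#' @param rate sampling rate, Hz.
#' @param lags_ms lag grid, ms; default -60 to +60 in 10-ms steps.
#' @return data.frame with columns `lag_ms`, `r`, `z`; `r` is `NA` at lags
#'   where either sub-segment has zero variance.
#' @export
lagged_correlation <- function(head, bow, rate = 100,
                               lags_ms = seq(-60, 60, by = 10)) {
  n <- length(head)
  if (length(bow) != n) stop("head and bow windows differ in length",
                             call. = FALSE)
  if (anyNA(head) || anyNA(bow))
    stop("window contains missing samples", call. = FALSE)
  lag_samp <- round(lags_ms * rate / 1000)
  if (any(abs(lag_samp) >= n)) stop("lag exceeds window length", call. = FALSE)
  r <- vapply(lag_samp, function(l) {
    hi <- (max(1, 1 + l)):(min(n, n + l))
    bi <- hi - l
    h <- head[hi]; b <- bow[bi]
    if (sd(h) == 0 || sd(b) == 0) return(NA_real_)
    cor(h, b)
  }, numeric(1))
  data.frame(lag_ms = lags_ms, r = r, z = fisher_z(r))
}

# Vectorized form used by the take driver: head/bow are len x n_window
# matrices (one column per window). Returns an n_lag x n_window matrix of r.
lagged_correlation_matrix <- function(head, bow, rate = 100,
                                      lags_ms = seq(-60, 60, by = 10)) {
  n <- nrow(head)
  lag_samp <- round(lags_ms * rate / 1000)
  out <- matrix(NA_real_, length(lags_ms), ncol(head))
  for (k in seq_along(lag_samp)) {
    l <- lag_samp[k]
    hi <- (max(1, 1 + l)):(min(n, n + l))
    h <- head[hi, , drop = FALSE]
    b <- bow[hi - l, , drop = FALSE]
    hc <- sweep(h, 2, colMeans(h))
    bc <- sweep(b, 2, colMeans(b))
    den <- sqrt(colSums(hc^2) * colSums(bc^2))
    r <- colSums(hc * bc) / den
    r[den == 0] <- NA_real_
    out[k, ] <- r
  }
  out
}

#' Pick the peak of a windowed cross-correlation function
#'
#' The lag maximizing r among defined lags; ties are broken by the smallest
#' absolute lag, then by the negative lag.
#'
#' @param f data.frame from [lagged_correlation()] (columns `lag_ms`, `r`).
#' @return list with `peak_r`, `peak_z`, `lag_ms`, or `NULL` if every lag is
#'   undefined (window excluded).
#' @export
peak_pick <- function(f) {
  ok <- which(!is.na(f$r))
  if (!length(ok)) return(NULL)
  rmax <- max(f$r[ok])
  cand <- ok[f$r[ok] >= rmax - 1e-15]
  cand <- cand[order(abs(f$lag_ms[cand]), f$lag_ms[cand])]
  i <- cand[1]
  list(peak_r = f$r[i], peak_z = fisher_z(f$r[i]), lag_ms = f$lag_ms[i])
}

#' Aggregate per-window peaks into take-level coordination indices
#'
#' The four head-bow coordination indices of one take: peak correlation
#' (averaged on the Fisher-z scale, reported after tanh back-transform),
#' mean peak lag, mean absolute peak lag, and the standard deviation of the
#' peak lags across windows (coordination stability).
#'
#' @param peaks data.frame with one row per window, columns `peak_z`,
#'   `lag_ms`.
#' @return object of class `coord_indices`: list with `peak_r`, `mean_lag_ms`,
#'   `mean_abs_lag_ms`, `lag_sd_ms` (NA, flagged, with fewer than 2 windows),
#'   `n_windows`.
#' @export
aggregate_take <- function(peaks) {
  stopifnot(nrow(peaks) >= 1)
  structure(list(peak_r = fisher_z_inv(mean(peaks$peak_z)),
                 mean_lag_ms = mean(peaks$lag_ms),
                 mean_abs_lag_ms = mean(abs(peaks$lag_ms)),
                 lag_sd_ms = if (nrow(peaks) >= 2) sd(peaks$lag_ms) else NA_real_,
                 n_windows = nrow(peaks)),
            class = "coord_indices")
}

#' @export
print.coord_indices <- function(x, ...) {
  cat(sprintf(paste0("head-bow coordination over %d windows: peak r %.3f, ",
                     "mean lag %.1f ms, mean |lag| %.1f ms, lag sd %.1f ms\n"),
              x$n_windows, x$peak_r, x$mean_lag_ms, x$mean_abs_lag_ms,
              x$lag_sd_ms))
  invisible(x)
}

#' Windowed cross-correlation analysis of one take
#'
#' Slides 1-s windows (50% overlap) within each passage of a preprocessed
#' trial, computes the lagged cross-correlation function per window, picks
#' peaks and aggregates the take-level indices. Windows containing missing
#' samples are dropped.
#'
#' @param pre a `preprocessed_trial` from [preprocess_trial()].
#' @param lags_ms lag grid, ms.
#' @param length_ms,overlap window parameters.
#' @return list with `indices` (a `coord_indices`), `windows` (per-window
#'   data.frame: passage, start_s, peak_r, peak_z, lag_ms) and
#'   `mean_function` (per-lag z-averaged correlation function, tanh-backed).
#' @export
windowed_xcorr_take <- function(pre, lags_ms = seq(-60, 60, by = 10),
                                length_ms = 1000, overlap = 0.5) {
  rate <- pre$rate
  rows <- list()
  zsum <- NULL
  for (pn in names(passage_list(pre))) {
    p <- pre[[pn]]
    w <- slide_windows(length(p$head_speed), rate, length_ms, overlap)
    if (!nrow(w)) next
    keep <- vapply(seq_len(nrow(w)), function(i) {
      idx <- w$start[i]:w$end[i]
      !anyNA(p$head_speed[idx]) && !anyNA(p$bow_speed[idx])
    }, logical(1))
    w <- w[keep, , drop = FALSE]
    if (!nrow(w)) next
    len <- w$end[1] - w$start[1] + 1L
    hm <- vapply(seq_len(nrow(w)),
                 function(i) p$head_speed[w$start[i]:w$end[i]], numeric(len))
    bm <- vapply(seq_len(nrow(w)),
                 function(i) p$bow_speed[w$start[i]:w$end[i]], numeric(len))
    rmat <- lagged_correlation_matrix(hm, bm, rate, lags_ms)
    zmat <- fisher_z(rmat)
    zsum <- if (is.null(zsum)) rowSums(zmat, na.rm = TRUE) else
      zsum + rowSums(zmat, na.rm = TRUE)
    for (i in seq_len(ncol(rmat))) {
      pk <- peak_pick(data.frame(lag_ms = lags_ms, r = rmat[, i]))
      if (is.null(pk)) next
      rows[[length(rows) + 1L]] <-
        data.frame(passage = pn, start_s = p$start_s + (w$start[i] - 1) / rate,
                   peak_r = pk$peak_r, peak_z = pk$peak_z, lag_ms = pk$lag_ms)
    }
  }
  if (!length(rows))
    return(list(indices = NULL, windows = NULL, mean_function = NULL))
  windows <- do.call(rbind, rows)
  list(indices = aggregate_take(windows),
       windows = windows,
       mean_function = data.frame(lag_ms = lags_ms,
                                  r = fisher_z_inv(zsum / nrow(windows))))
}
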