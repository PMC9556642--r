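#' Average the three head-cap markers
#'
#' Coordinate-wise mean of the three cap markers; with rigid marker offsets
#' this recovers the head-centre trajectory (plus measurement noise reduced
#' by sqrt(3)). A sample is missing in the output iff it is missing in any
#' input marker.
#'
#' @param m1,m2,m3 n x 3 numeric matrices (mm), `NA` for missing samples.
#' @return n x 3 matrix.
#' @export
average_head_markers <- function(m1, m2, m3) {
  if (!all(dim(m1) == dim(m2)) || !all(dim(m1) == dim(m3)))
    stop("marker trajectories must have identical dimensions", call. = FALSE)
  (m1 + m2 + m3) / 3
}

# run-length encode missingness of one coordinate column
na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Interpolate short occlusion gaps
#'
#' Contiguous runs of missing samples strictly shorter than `max_gap_ms`
#' (at 100 Hz: up to 4 samples; a 5-sample, 50-ms gap is left missing) are
#' replaced by cubic interpolation per coordinate. Longer runs, and runs
#' touching either end of the recording, are left missing. Present samples
#' are never altered.
#'
#' @param traj n x 3 numeric matrix (or numeric vector), `NA` for missing.
#' @param rate sampling rate, Hz.
#' @param max_gap_ms gaps strictly shorter than this are filled. Default 50.
#' @return object of the same shape with short gaps filled.
#' @export
fill_short_gaps <- function(traj, rate = 100, max_gap_ms = 50) {
  vec <- is.null(dim(traj))
  m <- if (vec) matrix(traj, ncol = 1) else traj
  max_len <- ceiling(max_gap_ms * rate / 1000) - 1L   # strictly shorter
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (!anyNA(x)) next
    runs <- na_runs(x)
    present <- which(!is.na(x))
    if (length(present) < 2) next
    for (i in seq_len(nrow(runs))) {
      len <- runs$end[i] - runs$start[i] + 1L
      if (len > max_len) next
      if (runs$start[i] == 1L || runs$end[i] == length(x)) next  # edge gaps
      idx <- runs$start[i]:runs$end[i]
      m[idx, j] <- spline(present, x[present], xout = idx)$y
    }
  }
  if (vec) m[, 1] else m
}

#' Scalar speed of a marker trajectory
#'
#' Euclidean distance between successive positions times the sampling rate
#' (mm/s). The speed sample at index t carries the timestamp of position t
#' (left-aligned); the series is one sample shorter than the positions.
#' A speed sample is missing if either endpoint position is missing.
#'
#' @param traj n x 3 numeric matrix, mm.
#' @param rate sampling rate, Hz.
#' @return numeric vector of length n - 1, mm/s.
#' @export
compute_speed <- function(traj, rate = 100) {
  if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
  if (nrow(traj) < 2) stop("need at least 2 samples", call. = FALSE)
  d <- diff(traj)
  sqrt(rowSums(d^2)) * rate
}

#' Z-score a series over its present samples
#'
#' Centring and scaling use the mean and sample standard deviation of the
#' non-missing samples of the segment (one musical passage in the standard
#' pipeline); missing samples stay missing.
#'
#' @param x numeric vector, `NA` allowed.
#' @return z-scored vector.
#' @export
zscore_segment <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 present samples", call. = FALSE)
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("zero variance segment cannot be z-scored", call. = FALSE)
  (x - mean(x[ok])) / s
}

#' Zero-phase Butterworth band-pass
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift. The default 0.5-12 Hz band
#' brackets the metrical frequencies of the performance (whole notes near
#' 1 Hz up to eighth notes near 8 Hz).
#'
#' @param x numeric vector without missing samples.
#' @param low,high band edges, Hz.
#' @param rate sampling rate, Hz.
#' @param order filter order (per pass). Default 2.
#' @return filtered vector, same length.
#' @export
bandpass <- function(x, low = 0.5, high = 12, rate = 100, order = 2) {
  if (anyNA(x)) stop("bandpass input must not contain missing samples",
                     call. = FALSE)
  stopifnot(low > 0, high > low, high < rate / 2)
  min_len <- 3 * (2 * order + 1)
  if (length(x) < min_len)
    stop("segment too short to filter (need >= ", min_len, " samples)",
         call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# z-score then band-pass one passage's speed series, filtering each
# contiguous non-missing run separately; runs too short to filter are
# dropped (left missing), per the window-drop rule.
clean_speed_segment <- function(sp, rate = 100, band = c(0.5, 12)) {
  z <- zscore_segment(sp)
  out <- rep(NA_real_, length(z))
  runs <- rle(!is.na(z))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  min_len <- 3 * 5
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    if (length(idx) < min_len) next
    out[idx] <- bandpass(z[idx], band[1], band[2], rate)
  }
  out
}

# sample extent [start, end] of each passage on the trial clock
passage_extents <- function(grid, passages, rate = 100) {
  pid <- sort(unique(passages$passage))
  out <- lapply(pid, function(p) {
    seg <- passages[passages$passage == p, ]
    first <- min(seg$first_step); last <- max(seg$last_step)
    t0 <- grid$onset_s[first]
    t1 <- grid$onset_s[last] + grid$duration_s[last]
    c(start = floor(t0 * rate) + 1L, end = floor(t1 * rate))
  })
  names(out) <- paste0("passage", pid)
  out
}

#' Preprocess one trial into per-passage speed series
#'
#' Runs the fixed preprocessing chain: average the three cap markers, fill
#' short occlusion gaps (< 50 ms) cubically, compute scalar speed, then for
#' each playable passage z-score the speed over the passage and band-pass
#' filter it (zero-phase Butterworth, 0.5-12 Hz). Filtering is applied per
#' passage (never across pauses). Positions are also returned (gap-filled,
#' unfiltered) for the spatial descriptors.
#'
#' @param trial a `synthetic_trial`, or a list with `head_markers` (list of
#'   three n x 3 matrices), `bow` (n x 3), `beat_grid`, `passages`, `rate`.
#' @param band band-pass edges, Hz.
#' @return list of class `preprocessed_trial`: per passage a list with
#'   `head_speed`, `bow_speed` (cleaned, unitless), `head_pos`, `bow_pos`
#'   (mm), `start_s`, `rate`; plus `beat_grid` and `passages`.
#' @export
preprocess_trial <- function(trial, band = c(0.5, 12)) {
  rate <- trial$rate %||% 100
  centre <- average_head_markers(trial$head_markers[[1]],
                                 trial$head_markers[[2]],
                                 trial$head_markers[[3]])
  centre <- fill_short_gaps(centre, rate)
  bow <- fill_short_gaps(trial$bow, rate)
  head_speed <- compute_speed(centre, rate)
  bow_speed <- compute_speed(bow, rate)
  ext <- passage_extents(trial$beat_grid, trial$passages, rate)
  passes <- lapply(ext, function(e) {
    idx <- e["start"]:min(e["end"], length(head_speed))
    list(head_speed = clean_speed_segment(head_speed[idx], rate, band),
         bow_speed = clean_speed_segment(bow_speed[idx], rate, band),
         head_pos = centre[idx, , drop = FALSE],
         bow_pos = bow[idx, , drop = FALSE],
         start_s = (idx[1] - 1) / rate,
         rate = rate)
  })
  structure(c(passes, list(beat_grid = trial$beat_grid,
                           passages = trial$passages, rate = rate)),
            class = "preprocessed_trial")
}

passage_list <- function(pre) pre[grep("^passage[0-9]+$", names(pre))]
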