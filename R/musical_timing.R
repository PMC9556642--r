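#' Derive the inter-beat interval series from a beat grid
#'
#' The annotation marks half-note step onsets (two beats per step), so each
#' step duration divided by two yields two equal inter-beat intervals (IBIs).
#' Only pairs of consecutive played steps contribute; pairs spanning a pause
#' are excluded.
#'
#' @param grid a `beat_grid`.
#' @return numeric vector of IBIs, ms, with attribute `onset_s` giving the
#'   onset time of each IBI (step onset and step midpoint).
#' @export
derive_ibis <- function(grid) {
  if (any(diff(grid$onset_s) <= 0))
    stop("beat-grid onsets must be strictly increasing", call. = FALSE)
  n <- nrow(grid)
  consec <- which(diff(grid$step_index) == 1L &
                  grid$played[-n] & grid$played[-1])
  if (length(consec) < 1)
    stop("need at least 2 consecutive played steps", call. = FALSE)
  dur <- grid$onset_s[consec + 1L] - grid$onset_s[consec]
  ibi <- rep(dur / 2 * 1000, each = 2)
  onset <- as.numeric(rbind(grid$onset_s[consec], grid$onset_s[consec] + dur / 2))
  attr(ibi, "onset_s") <- onset
  ibi
}

#' Take-level tempo summary
#'
#' Take length (first onset to the end of the last step), mean IBI, tempo in
#' bpm (`60000 / mean IBI`) and tempo variability as the coefficient of
#' variation (sample sd / mean) of the IBI series.
#'
#' @param grid a `beat_grid`.
#' @return object of class `tempo_summary`: list with `take_length_s`,
#'   `mean_ibi_ms`, `bpm`, `cv`.
#' @export
tempo_summary <- function(grid) {
  ibi <- derive_ibis(grid)
  n <- nrow(grid)
  last_dur <- if (!is.null(grid$duration_s)) grid$duration_s[n] else
    grid$onset_s[n] - grid$onset_s[n - 1]
  mean_ibi <- mean(ibi)
  structure(list(take_length_s = grid$onset_s[n] + last_dur - grid$onset_s[1],
                 mean_ibi_ms = mean_ibi,
                 bpm = 60000 / mean_ibi,
                 cv = sd(ibi) / mean_ibi),
            class = "tempo_summary")
}

#' @export
print.tempo_summary <- function(x, ...) {
  cat(sprintf("take length %.1f s, mean IBI %.1f ms (%.1f bpm), IBI CV %.4f\n",
              x$take_length_s, x$mean_ibi_ms, x$bpm, x$cv))
  invisible(x)
}

#' Locally tempo-matched metrical frequencies
#'
#' Averages the IBIs whose onsets fall in `[window[1], window[2])` and
#' converts to the frequency of the quarter-note (beat) level; the other
#' levels follow the octave ladder (whole = quarter / 4, half = quarter / 2,
#' eighth = quarter * 2). If the window contains no IBI onset the take-level
#' mean IBI is used and the result is flagged via attribute `fallback`.
#'
#' @param grid a `beat_grid`.
#' @param window numeric length-2, `(start, end)` seconds on the trial clock.
#' @return named numeric (`whole`, `half`, `quarter`, `eighth`), Hz, of
#'   class `metrical_freqs`.
#' @export
local_metrical_frequencies <- function(grid, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ibi <- derive_ibis(grid)
  onset <- attr(ibi, "onset_s")
  sel <- onset >= window[1] & onset < window[2]
  fallback <- !any(sel)
  m <- if (fallback) mean(ibi) else mean(ibi[sel])
  f_quarter <- 1000 / m
  out <- c(whole = f_quarter / 4, half = f_quarter / 2,
           quarter = f_quarter, eighth = f_quarter * 2)
  attr(out, "fallback") <- fallback
  class(out) <- "metrical_freqs"
  out
}
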