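#' Analysis configuration
#'
#' All tunable parameters of the analysis chain in one validated list. The
#' defaults are the standard protocol: 100 Hz sampling, 0.5-12 Hz speed
#' band, 1-s cross-correlation windows with 50% overlap and a +/-60 ms lag
#' grid in 10-ms steps, 3-s non-overlapping spectral windows zero-padded to
#' 512 points, and +/-0.5 Hz phase bands around the tempo-matched metrical
#' frequencies.
#'
#' @param rate sampling rate, Hz.
#' @param band speed band-pass edges, Hz.
#' @param xcorr_window_ms,xcorr_overlap cross-correlation window length and
#'   fractional overlap.
#' @param lags_ms lag grid, ms.
#' @param psd_window_s spectral window length, s.
#' @param nfft zero-padding target for spectral and phase analysis.
#' @param phase_halfwidth half bandwidth of the phase bands, Hz.
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(rate = 100, band = c(0.5, 12),
                            xcorr_window_ms = 1000, xcorr_overlap = 0.5,
                            lags_ms = seq(-60, 60, by = 10),
                            psd_window_s = 3, nfft = 512,
                            phase_halfwidth = 0.5) {
  stopifnot(rate > 0, length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < rate / 2, xcorr_window_ms > 0,
            xcorr_overlap >= 0, xcorr_overlap < 1,
            length(lags_ms) >= 1, all(diff(lags_ms) > 0),
            psd_window_s > 0, nfft >= 64, phase_halfwidth > 0)
  structure(list(rate = rate, band = band,
                 xcorr_window_ms = xcorr_window_ms,
                 xcorr_overlap = xcorr_overlap, lags_ms = lags_ms,
                 psd_window_s = psd_window_s, nfft = nfft,
                 phase_halfwidth = phase_halfwidth),
            class = "analysis_config")
}

#' Analyze one take end to end
#'
#' Runs preprocessing and every analysis stage on one trial and returns the
#' full set of take-level measures: tempo summary, the four windowed
#' cross-correlation indices, spatial descriptors for head and bow, power
#' at the four metrical levels (P1-P4) for head and bow, head-bow power
#' correlations, and the phase-coupling statistics (VL, MA, MAA) per level.
#'
#' @param trial a `synthetic_trial` (or compatible list, see
#'   [preprocess_trial()]).
#' @param config an [analysis_config()].
#' @return data.frame with columns `measure`, `value`.
#' @export
analyze_trial <- function(trial, config = analysis_config()) {
  pre <- preprocess_trial(trial, band = config$band)
  ts <- tempo_summary(trial$beat_grid)
  xc <- windowed_xcorr_take(pre, lags_ms = config$lags_ms,
                            length_ms = config$xcorr_window_ms,
                            overlap = config$xcorr_overlap)
  sp_h <- spatial_take_summary(pre, "head",
                               length_ms = config$xcorr_window_ms,
                               overlap = config$xcorr_overlap)
  sp_b <- spatial_take_summary(pre, "bow",
                               length_ms = config$xcorr_window_ms,
                               overlap = config$xcorr_overlap)
  pw_h <- metrical_power_take(pre, "head", nfft = config$nfft)
  pw_b <- metrical_power_take(pre, "bow", nfft = config$nfft)
  pc <- power_correlation(pw_h, pw_b)
  ph <- phase_coupling_take(pre, halfwidth = config$phase_halfwidth,
                            nfft = config$nfft)

  plab <- stats::setNames(paste0("P", 1:4), METRICAL_LEVELS)
  level_mean <- function(df, lev) mean(df$power[df$level == lev])
  vals <- c(
    take_length_s = ts$take_length_s, mean_ibi_ms = ts$mean_ibi_ms,
    bpm = ts$bpm, ibi_cv = ts$cv,
    peak_r = xc$indices$peak_r, mean_lag_ms = xc$indices$mean_lag_ms,
    mean_abs_lag_ms = xc$indices$mean_abs_lag_ms,
    lag_sd_ms = xc$indices$lag_sd_ms,
    head_interdistance_mm = sp_h$mean_interdistance_mm,
    head_hull_cm3 = sp_h$hull_volume_cm3,
    bow_interdistance_mm = sp_b$mean_interdistance_mm,
    bow_hull_cm3 = sp_b$hull_volume_cm3)
  for (lev in METRICAL_LEVELS) {
    vals[paste0("head_power_", plab[lev])] <- level_mean(pw_h, lev)
    vals[paste0("bow_power_", plab[lev])] <- level_mean(pw_b, lev)
    vals[paste0("power_corr_", plab[lev])] <- pc$r[pc$level == lev]
    vals[paste0("VL_", plab[lev])] <- ph$VL[ph$level == lev]
    vals[paste0("MA_", plab[lev])] <- ph$MA[ph$level == lev]
    vals[paste0("MAA_", plab[lev])] <- ph$MAA[ph$level == lev]
  }
  data.frame(measure = names(vals), value = as.numeric(vals),
             row.names = NULL)
}

#' Analyze a whole study
#'
#' Applies [analyze_trial()] to every trial of a dataset and binds the
#' results into one tidy measure table.
#'
#' @param dataset list with `trials` and `meta` as returned by
#'   [generate_dataset()] (or assembled from files).
#' @param config an [analysis_config()].
#' @return data.frame with columns `violinist`, `condition`, `take`,
#'   `measure`, `value`.
#' @export
analyze_study <- function(dataset, config = analysis_config()) {
  out <- lapply(seq_along(dataset$trials), function(i) {
    m <- analyze_trial(dataset$trials[[i]], config)
    cbind(dataset$meta[rep(i, nrow(m)), c("violinist", "condition", "take")],
          m, row.names = NULL)
  })
  do.call(rbind, out)
}

# stable polynomial rolling hash of a deparsed R object, for the manifest
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline: simulate, analyze, compare
#'
#' Generates a synthetic study, analyzes every trial, compares conditions
#' for each measure with the replicated-block Friedman test, and assembles
#' a run manifest (seeds, configuration hashes, counts, package version).
#' Deterministic for fixed design, config and seed. No multiple-comparison
#' correction is applied to the per-measure p-values.
#'
#' @param design a [study_design()].
#' @param config an [analysis_config()].
#' @param seed master seed for the simulation.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV/JSON via [write_results()].
#' @return list of class `pipeline_result`: `measures` (tidy measure
#'   table), `comparison` (per-measure condition comparison), `manifest`.
#' @export
run_pipeline <- function(design = study_design(), config = analysis_config(),
                         seed = 1L, out_dir = NULL) {
  dataset <- generate_dataset(design, seed)
  measures <- analyze_study(dataset, config)
  comparison <- compare_conditions(measures)
  manifest <- list(
    package_version = as.character(utils::packageVersion("headbow")),
    seed = as.integer(seed),
    design_hash = config_hash(design),
    config_hash = config_hash(config),
    n_trials = length(dataset$trials),
    n_measures = length(unique(measures$measure)),
    created = "run manifest; seeds and hashes make the run reproducible")
  res <- structure(list(measures = measures, comparison = comparison,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d trials, %d measures\n",
              x$manifest$seed, x$manifest$n_trials, x$manifest$n_measures))
  sig <- x$comparison[x$comparison$p < 0.05, "measure"]
  cat("measures with p < 0.05:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
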