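# File formats: marker tables are TSV/CSV with a `time_s` column followed
# by `<marker>_x`, `<marker>_y`, `<marker>_z` triplets in mm; missing
# samples are empty fields. Beat annotations are CSV with columns
# take_id, step_index, onset_s, bar, played. Qualisys-style exports with a
# metadata preamble are handled by skipping leading lines whose first token
# is not the header or a number.

MARKER_NAMES <- c("head1", "head2", "head3", "bow")

#' Write and read marker trajectory tables
#'
#' `write_marker_table` writes one trial's four markers (three head-cap
#' markers and the bow tip) as a tab-separated table; missing samples
#' become empty fields. `read_marker_table` parses the same dialect (tab or
#' comma separated), skipping any metadata preamble before the header line,
#' and reports malformed rows with their line numbers.
#'
#' @param trial a `synthetic_trial` (or list with `time_s`, `head_markers`,
#'   `bow`).
#' @param path file path.
#' @param sep field separator for writing, `"\t"` or `","`.
#' @return `read_marker_table` returns a list with `time_s`,
#'   `head_markers` (list of three n x 3 matrices), `bow` (n x 3 matrix)
#'   and `rate` (Hz, inferred from the time column).
#' @export
write_marker_table <- function(trial, path, sep = "\t") {
  m <- cbind(trial$head_markers[[1]], trial$head_markers[[2]],
             trial$head_markers[[3]], trial$bow)
  colnames(m) <- paste0(rep(MARKER_NAMES, each = 3), "_", c("x", "y", "z"))
  df <- data.frame(time_s = trial$time_s, m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  lines <- readLines(path)
  sep <- if (grepl("\t", lines[min(which(grepl("time_s", lines)))])) "\t" else ","
  hdr_i <- which(grepl("(^|[\t,])time_s([\t,]|$)", lines))[1]
  if (is.na(hdr_i)) stop("no header with a time_s column found in ", path,
                         call. = FALSE)
  header <- strsplit(lines[hdr_i], sep, fixed = TRUE)[[1]]
  expected <- c("time_s",
                paste0(rep(MARKER_NAMES, each = 3), "_", c("x", "y", "z")))
  unknown <- setdiff(header, expected)
  if (length(unknown))
    stop("unknown marker columns: ", paste(unknown, collapse = ", "),
         "; expected ", paste(expected, collapse = ", "), call. = FALSE)
  if (!all(expected %in% header))
    stop("missing marker columns: ",
         paste(setdiff(expected, header), collapse = ", "), call. = FALSE)
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(cells)
  # trailing empty fields are dropped by strsplit; pad, but flag rows with
  # partial coordinate triplets below
  bad <- which(nf > length(header))
  if (length(bad))
    stop("malformed row(s) at line(s) ",
         paste(hdr_i + bad, collapse = ", "), ": too many fields",
         call. = FALSE)
  vals <- matrix(NA_real_, length(cells), length(header))
  for (i in seq_along(cells)) {
    v <- cells[[i]]
    v[!nzchar(v)] <- NA
    vals[i, seq_along(v)] <- suppressWarnings(as.numeric(v))
    if (any(nzchar(cells[[i]]) & is.na(vals[i, seq_along(v)])))
      stop("malformed row at line ", hdr_i + i, ": non-numeric field",
           call. = FALSE)
  }
  colnames(vals) <- header
  # a sample must have all three coordinates of a marker or none
  for (mk in MARKER_NAMES) {
    cols <- paste0(mk, "_", c("x", "y", "z"))
    nna <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    if (any(nna %in% c(1, 2)))
      stop("malformed row at line ",
           hdr_i + which(nna %in% c(1, 2))[1],
           ": partial coordinate triplet for marker ", mk, call. = FALSE)
  }
  tm <- vals[, "time_s"]
  rate <- 1 / stats::median(diff(tm))
  grab <- function(mk) {
    m <- vals[, paste0(mk, "_", c("x", "y", "z")), drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  }
  list(time_s = tm,
       head_markers = list(grab("head1"), grab("head2"), grab("head3")),
       bow = grab("bow"), rate = rate)
}

#' Write and read beat annotation tables
#'
#' CSV with columns `take_id`, `step_index`, `onset_s`, `bar`, `played`;
#' steps are half-note segments, `played` marks steps inside playable
#' passages.
#'
#' @param grid a `beat_grid`.
#' @param path file path.
#' @param take_id identifier written in the `take_id` column.
#' @return `read_beat_annotations` returns a `beat_grid`.
#' @export
write_beat_annotations <- function(grid, path, take_id = "take1") {
  df <- data.frame(take_id = take_id, step_index = grid$step_index,
                   onset_s = grid$onset_s, bar = grid$bar,
                   played = as.integer(grid$played))
  if (!is.null(grid$duration_s)) df$duration_s <- grid$duration_s
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_annotations
#' @export
read_beat_annotations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("step_index", "onset_s", "bar", "played")
  if (!all(need %in% names(df)))
    stop("beat annotation file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(diff(df$onset_s) <= 0))
    stop("beat onsets must be strictly increasing", call. = FALSE)
  grid <- data.frame(step_index = df$step_index, onset_s = df$onset_s,
                     bar = df$bar, played = as.logical(df$played))
  if ("duration_s" %in% names(df)) grid$duration_s <- df$duration_s
  class(grid) <- c("beat_grid", "data.frame")
  grid
}

#' Write ground truth and result tables
#'
#' `write_ground_truth` stores a synthetic trial's generating parameters as
#' JSON next to the data files. `write_results` writes the tidy measure
#' table and the condition comparison as CSV plus the run manifest and the
#' comparison as JSON.
#'
#' @param trial a `synthetic_trial`.
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param path,dir output file / directory.
#' @export
write_ground_truth <- function(trial, path) {
  gt <- trial$ground_truth
  jsonlite::write_json(list(
    profile = unclass(gt$profile), head_bow_lag_ms = gt$head_bow_lag_ms,
    mean_ibi_ms = mean(gt$ibi_ms), n_missing = gt$n_missing,
    seed = gt$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$comparison, file.path(dir, "comparison.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read or write a study configuration as YAML
#'
#' The YAML mirrors the arguments of [analysis_config()]; unknown keys are
#' rejected so typos fail loudly before any computation.
#'
#' @param path YAML file path.
#' @param config an `analysis_config` to write.
#' @return `read_analysis_config` returns an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(analysis_config, y)
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
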