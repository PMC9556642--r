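#' Mean pairwise distance of a 3D point cloud
#'
#' Spatial dispersion of the positions visited within one analysis window:
#' the mean Euclidean distance over all unordered pairs of points.
#'
#' @param points n x 3 numeric matrix, mm.
#' @return mean inter-distance, mm.
#' @export
mean_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  mean(stats::dist(points))
}

#' Volume of the 3D convex hull of a point cloud
#'
#' The volume of the smallest convex polyhedron containing all points,
#' converted from mm^3 to cm^3. Degenerate point sets (collinear or
#' coplanar) return 0.
#'
#' @param points n x 3 numeric matrix (n >= 4), mm.
#' @return hull volume, cm^3.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points", call. = FALSE)
  stop_if_not_finite(points, "hull points")
  .hull_volume_cpp(points) / 1000
}

#' Spatial descriptors of one take
#'
#' Computes both amplitude descriptors in each 1-s analysis window of each
#' passage of the raw (gap-filled, unfiltered) trajectory and averages them
#' across windows. Windows containing missing samples, or with too few
#' points for a hull, are dropped.
#'
#' @param pre a `preprocessed_trial`.
#' @param effector `"head"` (marker-averaged centre) or `"bow"`.
#' @param length_ms,overlap window parameters (same grid as the windowed
#'   cross-correlation).
#' @return list with `mean_interdistance_mm`, `hull_volume_cm3` (take-level
#'   means), `n_windows` and the per-window data.frame `windows`.
#' @export
spatial_take_summary <- function(pre, effector = c("head", "bow"),
                                 length_ms = 1000, overlap = 0.5) {
  effector <- match.arg(effector)
  rate <- pre$rate
  rows <- list()
  for (pn in names(passage_list(pre))) {
    p <- pre[[pn]]
    pos <- if (effector == "head") p$head_pos else p$bow_pos
    w <- slide_windows(nrow(pos), rate, length_ms, overlap)
    for (i in seq_len(nrow(w))) {
      pts <- pos[w$start[i]:w$end[i], , drop = FALSE]
      if (anyNA(pts)) next
      rows[[length(rows) + 1L]] <- data.frame(
        passage = pn, start_s = p$start_s + (w$start[i] - 1) / rate,
        mean_interdistance_mm = mean_pairwise_distance(pts),
        hull_volume_cm3 = convex_hull_volume(pts))
    }
  }
  if (!length(rows))
    return(list(mean_interdistance_mm = NA_real_, hull_volume_cm3 = NA_real_,
                n_windows = 0L, windows = NULL))
  windows <- do.call(rbind, rows)
  list(mean_interdistance_mm = mean(windows$mean_interdistance_mm),
       hull_volume_cm3 = mean(windows$hull_volume_cm3),
       n_windows = nrow(windows), windows = windows)
}
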