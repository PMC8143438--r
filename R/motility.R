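#' Per-track motility metrics
#'
#' Computes, for every track in a long-format table, the standard per-cell
#' track statistics used to describe interstitial migration:
#'
#' * `path_length` — total track length, the sum of Euclidean 3D step
#'   lengths between consecutive observed points (um). Frame gaps are
#'   bridged by the single straight segment between the flanking points,
#'   which slightly underestimates the true path; no positions are
#'   fabricated.
#' * `displacement` — straight-line distance from first to last point (um).
#' * `duration` — elapsed time from first to last point (minutes).
#' * `mean_velocity` — `path_length / duration` (um/min). This is the
#'   gap-robust path-based definition, equivalent to the mean of per-step
#'   speeds only under uniform frame intervals.
#' * `confinement` — the confinement ratio `displacement / path_length`,
#'   in \[0, 1\]: 1 for perfectly straight motion, near 0 for a cell that
#'   returned to its origin. A cell that never moved (`path_length == 0`)
#'   has an indeterminate ratio (0/0); by convention it is assigned 0, which
#'   is inconsequential downstream because its velocity is also 0 and it is
#'   static under any velocity threshold.
#'
#' Tracks shorter than `min_points` points or `min_duration` minutes are
#' rejected rather than measured; every rejection is recorded with its
#' reason in the `"rejections"` attribute (see [rejections()]). The default
#' filters exclude noise tracks of a few points; set both to 0 to measure
#' everything.
#'
#' @param tracks Long-format track table (see [read_tracks()]); validated on
#'   entry.
#' @param min_points Minimum number of points per track (default 5).
#' @param min_duration Minimum track duration in minutes (default 5).
#' @return A tibble with one row per retained track: `track_id`, `n_points`,
#'   `duration`, `path_length`, `displacement`, `mean_velocity`,
#'   `confinement`, plus any `mouse` / `fov` / `group` metadata. The
#'   rejection log is attached as attribute `"rejections"`.
#' @export
#' @examples
#' tr <- tibble::tibble(track_id = "a", frame = 0:2, t_s = c(0, 60, 120),
#'                      x_um = c(0, 3, 6), y_um = 0, z_um = 0)
#' metrics_table(tr, min_points = 0, min_duration = 0)
metrics_table <- function(tracks, min_points = 5, min_duration = 5) {
  stopifnot(min_points >= 0, min_duration >= 0)
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(track_id = character(), n_points = integer(),
                          duration = numeric(), path_length = numeric(),
                          displacement = numeric(), mean_velocity = numeric(),
                          confinement = numeric())
    attr(out, "rejections") <- tibble::tibble(track_id = character(),
                                              reason = character())
    return(out)
  }
  tracks <- validate_track_table(tracks)
  meta_present <- intersect(META_COLS, names(tracks))

  m <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      duration = (max(.data$t_s) - min(.data$t_s)) / 60,
      path_length = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2 +
                               diff(.data$z_um)^2)),
      displacement = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                            (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2 +
                            (dplyr::last(.data$z_um) - dplyr::first(.data$z_um))^2),
      dplyr::across(dplyr::all_of(meta_present), dplyr::first),
      .groups = "drop")

  if (any(m$duration <= 0)) {
    abort(sprintf("Zero duration with >= 2 points in track(s): %s",
                  paste(m$track_id[m$duration <= 0], collapse = ", ")),
          class = "ivtrack_computation_error")
  }
  m$mean_velocity <- m$path_length / m$duration
  # clamp guards against displacement/path_length exceeding 1 by rounding on
  # exactly collinear tracks; 0/0 convention for never-moved cells
  m$confinement <- ifelse(m$path_length > 0,
                          pmin(1, pmax(0, m$displacement / m$path_length)), 0)

  keep <- m$n_points >= min_points & m$duration >= min_duration
  rej <- m[!keep, , drop = FALSE]
  reasons <- character(nrow(rej))
  if (nrow(rej) > 0) {
    reasons <- ifelse(rej$n_points < min_points,
                      sprintf("too few points (%d < %d)", rej$n_points, min_points),
                      sprintf("too short (%.2f min < %g min)", rej$duration, min_duration))
    both <- rej$n_points < min_points & rej$duration < min_duration
    reasons[both] <- sprintf("too few points (%d < %d) and too short (%.2f min < %g min)",
                             rej$n_points[both], min_points, rej$duration[both], min_duration)
  }
  out <- m[keep, c("track_id", "n_points", "duration", "path_length",
                   "displacement", "mean_velocity", "confinement", meta_present)]
  attr(out, "rejections") <- tibble::tibble(track_id = rej$track_id, reason = reasons)
  out
}

#' Metrics for a single track
#'
#' Convenience wrapper around [metrics_table()] for one track. Returns the
#' one-row metrics tibble, or `NULL` (with the reason as a message) when the
#' track fails the filters.
#'
#' @inheritParams metrics_table
#' @param track Long-format table containing exactly one track.
#' @export
track_metrics <- function(track, min_points = 5, min_duration = 5) {
  if (length(unique(track$track_id)) != 1) {
    abort("track_metrics() expects exactly one track; use metrics_table() for many.",
          class = "ivtrack_validation_error")
  }
  m <- metrics_table(track, min_points = min_points, min_duration = min_duration)
  if (nrow(m) == 0) {
    rej <- attr(m, "rejections")
    inform(sprintf("Track '%s' rejected: %s", rej$track_id[1], rej$reason[1]))
    return(NULL)
  }
  attr(m, "rejections") <- NULL
  m
}

#' Rejection log of a metrics table
#'
#' @param metrics A metrics table from [metrics_table()].
#' @return Tibble of rejected tracks (`track_id`, `reason`).
#' @export
rejections <- function(metrics) {
  attr(metrics, "rejections") %||%
    tibble::tibble(track_id = character(), reason = character())
}
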