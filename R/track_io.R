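#' Read cell tracks from disk
#'
#' Reads track data in one of two dialects and returns a validated tidy
#' table.
#'
#' The `"long_csv"` dialect is the package's canonical schema, one row per
#' observed cell position: columns `track_id`, `frame`, `t_s` (seconds),
#' `x_um`, `y_um`, `z_um` (micrometres), plus optional metadata columns
#' `mouse`, `fov`, `group`. 2D exports may omit `z_um`; it is then set to 0
#' (all downstream geometry is 3D and degrades gracefully). Coordinates must
#' be physical micrometres — any pixel-to-micrometre conversion belongs in
#' whatever produced the file, since no universal calibration can be assumed.
#'
#' The `"per_track_summary"` dialect mirrors the one-row-per-track exports of
#' commercial tracking software: columns `track_id`,
#' `mean_velocity_um_min`, `displacement_um`, `track_length_um`, plus the
#' optional metadata columns.
#'
#' Validation enforces, per track: no duplicated frames, frames and times
#' strictly increasing, all coordinates finite. Missing frames (gaps) are
#' allowed and preserved; see [track_gaps()]. Points are returned sorted by
#' `track_id` then `frame`, never silently reordered otherwise.
#'
#' @param path Path to a CSV file (RFC-4180 style, UTF-8, `.` decimal
#'   separator).
#' @param dialect `"long_csv"` (default) or `"per_track_summary"`.
#' @return A tibble in the canonical schema of the dialect. An empty file
#'   yields an empty tibble with a warning.
#' @seealso [write_tracks()], [track_gaps()], [metrics_table()]
#' @export
read_tracks <- function(path, dialect = c("long_csv", "per_track_summary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Track file not found: '%s'", path), class = "ivtrack_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warn(sprintf("'%s' contains no track rows; returning an empty table.", path))
    return(empty_track_table(dialect))
  }
  if (dialect == "long_csv") {
    validate_track_table(tibble::as_tibble(df), context = path)
  } else {
    validate_summary_table(tibble::as_tibble(df), context = path)
  }
}

META_COLS <- c("mouse", "fov", "group")

empty_track_table <- function(dialect) {
  if (dialect == "long_csv") {
    tibble::tibble(track_id = character(), frame = integer(), t_s = numeric(),
                   x_um = numeric(), y_um = numeric(), z_um = numeric())
  } else {
    tibble::tibble(track_id = character(), mean_velocity_um_min = numeric(),
                   displacement_um = numeric(), track_length_um = numeric())
  }
}

#' Validate a long-format track table
#'
#' Checks the canonical long schema (see [read_tracks()]) and returns the
#' table sorted by track and frame. Called by the readers; exported so that
#' programmatically built tables can be checked the same way.
#'
#' @param tracks A data frame with the canonical long columns.
#' @param context Label used in error messages (e.g. a file name).
#' @return The validated, sorted tibble (with `z_um` filled in if absent).
#' @export
validate_track_table <- function(tracks, context = "tracks") {
  tracks <- tibble::as_tibble(tracks)
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(required, names(tracks))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  context, paste(missing, collapse = ", ")),
          class = "ivtrack_format_error")
  }
  if (!"z_um" %in% names(tracks)) {
    inform("No 'z_um' column: treating tracks as 2D, z set to 0.")
    tracks$z_um <- 0
  }
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  coords <- as.matrix(tracks[, c("t_s", "x_um", "y_um", "z_um")])
  if (!all(is.finite(coords))) {
    bad <- unique(tracks$track_id[rowSums(!is.finite(coords)) > 0])
    abort(sprintf("Non-finite time or coordinates in track(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "ivtrack_validation_error")
  }
  if (any(tracks$frame < 0)) {
    abort("Frame indices must be non-negative.", class = "ivtrack_validation_error")
  }
  if (any(tracks$t_s < 0)) {
    abort("Times must be non-negative.", class = "ivtrack_validation_error")
  }
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  dup <- duplicated(tracks[, c("track_id", "frame")])
  if (any(dup)) {
    abort(sprintf("Duplicated (track_id, frame) in track(s): %s",
                  paste(unique(tracks$track_id[dup]), collapse = ", ")),
          class = "ivtrack_validation_error")
  }
  # frames are now strictly increasing within track; times must be too
  bad_t <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(ok = all(diff(.data$t_s) > 0) || dplyr::n() < 2) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_t) > 0) {
    abort(sprintf("Time must strictly increase with frame; violated in track(s): %s",
                  paste(bad_t$track_id, collapse = ", ")),
          class = "ivtrack_validation_error")
  }
  n_per <- table(tracks$track_id)
  if (any(n_per < 2)) {
    abort(sprintf("Track(s) with fewer than 2 points: %s",
                  paste(names(n_per)[n_per < 2], collapse = ", ")),
          class = "ivtrack_validation_error")
  }
  tracks
}

validate_summary_table <- function(df, context = "summary") {
  required <- c("track_id", "mean_velocity_um_min", "displacement_um",
                "track_length_um")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  context, paste(missing, collapse = ", ")),
          class = "ivtrack_format_error")
  }
  df$track_id <- as.character(df$track_id)
  if (anyDuplicated(df$track_id)) {
    abort(sprintf("Duplicated track_id in '%s'.", context),
          class = "ivtrack_validation_error")
  }
  df
}

#' Write cell tracks to disk
#'
#' Writes the canonical long table, or a per-track metrics table in the
#' summary dialect (see [read_tracks()] for both schemas). Long tables
#' lacking `z_um` are written with `z_um = 0` and a note. Round-tripping
#' through [read_tracks()] reproduces coordinates to at least 6 decimal
#' places and all metadata.
#'
#' @param tracks Long-format track table, or for the summary dialect a
#'   metrics table as produced by [metrics_table()] (columns `track_id`,
#'   `mean_velocity`, `displacement`, `path_length`, metadata passthrough).
#' @param path Output CSV path.
#' @param dialect `"long_csv"` or `"per_track_summary"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, dialect = c("long_csv", "per_track_summary")) {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    if (nrow(tracks) > 0) {
      if (!"z_um" %in% names(tracks)) {
        inform("Tracks have no 'z_um' column; writing z_um = 0.")
        tracks$z_um <- 0
      }
      tracks <- validate_track_table(tracks, context = "tracks to write")
    } else {
      tracks <- empty_track_table("long_csv")
    }
    cols <- c("track_id", "frame", "t_s", "x_um", "y_um", "z_um",
              intersect(META_COLS, names(tracks)))
    out <- tracks[, cols]
  } else {
    if (nrow(tracks) == 0) {
      out <- empty_track_table("per_track_summary")
    } else {
      needed <- c("track_id", "mean_velocity", "displacement", "path_length")
      missing <- setdiff(needed, names(tracks))
      if (length(missing) > 0) {
        abort(sprintf("Metrics table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              class = "ivtrack_format_error")
      }
      out <- tibble::tibble(
        track_id = as.character(tracks$track_id),
        mean_velocity_um_min = tracks$mean_velocity,
        displacement_um = tracks$displacement,
        track_length_um = tracks$path_length)
      for (m in intersect(META_COLS, names(tracks))) out[[m]] <- tracks[[m]]
    }
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("Cannot write '%s': %s", path, conditionMessage(e)),
                              class = "ivtrack_io_error"))
  invisible(path)
}

#' Find frame gaps in tracks
#'
#' Lists runs of missing frames within each track, given the nominal frame
#' interval implied by consecutive frame indices. Gaps are reported, never
#' interpolated; the metrics layer bridges them with a single straight
#' segment.
#'
#' @param tracks Validated long-format track table.
#' @return A tibble with one row per gap: `track_id`, `after_frame`,
#'   `before_frame`, `n_missing`.
#' @export
track_gaps <- function(tracks) {
  tracks <- validate_track_table(tracks)
  per_track <- lapply(split(tracks, tracks$track_id), function(g) {
    d <- diff(g$frame)
    i <- which(d > 1)
    if (length(i) == 0) return(NULL)
    tibble::tibble(track_id = g$track_id[1],
                   after_frame = g$frame[i],
                   before_frame = g$frame[i + 1],
                   n_missing = d[i] - 1L)
  })
  out <- dplyr::bind_rows(per_track)
  if (nrow(out) == 0) {
    out <- tibble::tibble(track_id = character(), after_frame = integer(),
                          before_frame = integer(), n_missing = integer())
  }
  out
}
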