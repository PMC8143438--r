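#' Classification thresholds for migratory behaviour
#'
#' The velocity-versus-confinement plane is divided into four behavioural
#' quadrants by two thresholds: a migration velocity of 2 um/min — the speed
#' at which a cell moves more than about one cell width from its origin over
#' a 30-min recording — and a confinement ratio of 0.2, above which motion
#' is more likely directed. A value exactly at a threshold counts as "high"
#' (the motile definition is velocity >= 2 um/min; the confinement rule is
#' chosen to match, by symmetry).
#'
#' @param velocity Velocity threshold, um/min (default 2).
#' @param confinement Confinement-ratio threshold, dimensionless (default 0.2).
#' @return A `thresholds` object.
#' @export
thresholds <- function(velocity = 2, confinement = 0.2) {
  if (!is.finite(velocity) || velocity <= 0 ||
      !is.finite(confinement) || confinement <= 0) {
    abort("Thresholds must be finite and positive.", class = "ivtrack_config_error")
  }
  structure(list(velocity = velocity, confinement = confinement),
            class = "thresholds")
}

#' Behavioural quadrant of each track
#'
#' Assigns every track to one of four quadrants of the mean-velocity vs
#' confinement-ratio plane:
#'
#' * **Q1** — static: low velocity, low confinement.
#' * **Q2** — intermittent migration: low average velocity (below the
#'   motility threshold) but high confinement ratio.
#' * **Q3** — continuous migration: high velocity and high confinement.
#' * **Q4** — fast but confined: high velocity, low confinement — cells
#'   that move quickly yet stay near their origin.
#'
#' Note the field convention embedded here: because the confinement ratio
#' measures straightness, "intermittent" (Q2) cells are the slow ones whose
#' net motion is nonetheless directed, which can read counter-intuitively;
#' the labels follow the established quadrant semantics as stated rather
#' than reinterpret them.
#'
#' @param metrics Metrics table from [metrics_table()], or any data frame
#'   with `mean_velocity` and `confinement` columns.
#' @param th A [thresholds()] object.
#' @return The input with a `quadrant` factor column (`Q1`–`Q4`) appended.
#' @export
#' @examples
#' classify_tracks(tibble::tibble(mean_velocity = c(1, 3), confinement = c(0.1, 0.5)))
classify_tracks <- function(metrics, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  if (!all(c("mean_velocity", "confinement") %in% names(metrics))) {
    abort("classify_tracks() needs 'mean_velocity' and 'confinement' columns.",
          class = "ivtrack_validation_error")
  }
  hi_v <- metrics$mean_velocity >= th$velocity
  hi_c <- metrics$confinement >= th$confinement
  q <- dplyr::case_when(!hi_v & !hi_c ~ "Q1",
                        !hi_v &  hi_c ~ "Q2",
                         hi_v &  hi_c ~ "Q3",
                         hi_v & !hi_c ~ "Q4")
  metrics$quadrant <- factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
  metrics
}

#' Motile fraction of a cell population
#'
#' Percentage of cells that are motile, a motile cell being one with mean
#' velocity at or above the threshold (default 2 um/min). `level = "pooled"`
#' computes one percentage over all cells; `level = "mouse"` computes the
#' percentage within each mouse and returns the per-mouse values (average
#' them for a hierarchical group estimate).
#'
#' @inheritParams classify_tracks
#' @param level `"pooled"` (default) or `"mouse"`.
#' @return For `"pooled"`, a single percentage in \[0, 100\]; for
#'   `"mouse"`, a tibble with `mouse` and `motile_pct`.
#' @export
motile_fraction <- function(metrics, th = thresholds(), level = c("pooled", "mouse")) {
  level <- match.arg(level)
  if (nrow(metrics) == 0) {
    abort("Motile fraction is undefined for an empty collection.",
          class = "ivtrack_computation_error")
  }
  motile <- metrics$mean_velocity >= th$velocity
  if (level == "pooled") {
    return(100 * mean(motile))
  }
  if (!"mouse" %in% names(metrics) || anyNA(metrics$mouse)) {
    abort("level = 'mouse' requires a complete 'mouse' column.",
          class = "ivtrack_validation_error")
  }
  tibble::tibble(mouse = metrics$mouse, motile = motile) |>
    dplyr::group_by(.data$mouse) |>
    dplyr::summarise(motile_pct = 100 * mean(.data$motile), .groups = "drop")
}

#' Relative-frequency distribution of cell velocities
#'
#' Bins mean velocities into half-open intervals `[k*w, (k+1)*w)` of width
#' `w` and returns relative frequencies (summing to 1) together with the
#' median velocity, the two ingredients of the standard velocity-frequency
#' plot with its median arrow.
#'
#' @param velocities Numeric vector of mean velocities (um/min), or a
#'   metrics table with a `mean_velocity` column.
#' @param bin_width Bin width in um/min (default 0.5).
#' @return A list with `histogram` (tibble: `bin_left`, `bin_right`,
#'   `count`, `rel_freq`) and `median_velocity`.
#' @export
velocity_distribution <- function(velocities, bin_width = 0.5) {
  if (is.data.frame(velocities)) velocities <- velocities$mean_velocity
  if (length(velocities) == 0) {
    abort("Velocity distribution is undefined for empty input.",
          class = "ivtrack_computation_error")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("bin_width must be positive.", class = "ivtrack_config_error")
  }
  idx <- floor(velocities / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(k) sum(idx == k), integer(1))
  hist <- tibble::tibble(bin_left = rng * bin_width,
                         bin_right = (rng + 1) * bin_width,
                         count = counts,
                         rel_freq = counts / length(velocities))
  list(histogram = hist, median_velocity = median(velocities))
}

#' Hierarchical behaviour summaries
#'
#' Summarises quadrant occupancy the way grouped imaging experiments are
#' reported: quadrant percentages are computed within each field of view
#' (fov), fov values are averaged per mouse, and mouse values are averaged
#' per treatment group with the SEM over mice (sample SD / sqrt(n mice)) —
#' exactly this hierarchy, so a mouse with many cells does not dominate its
#' group.
#'
#' @inheritParams classify_tracks
#' @param level `"fov"`, `"mouse"` or `"group"`.
#' @return A tibble of summaries at the requested level. Fov and mouse
#'   levels carry quadrant percentages `pct_Q1`..`pct_Q4` (summing to 100),
#'   `motile_pct` (= `pct_Q3 + pct_Q4`), `median_velocity` and `n_tracks`;
#'   the group level carries `mean_*` and `sem_*` for each quadrant and the
#'   motile percentage, plus `n_mice` and `n_tracks`.
#' @export
summarize_behaviour <- function(metrics, th = thresholds(),
                                level = c("fov", "mouse", "group")) {
  level <- match.arg(level)
  needed <- switch(level, fov = c("group", "mouse", "fov"),
                   mouse = c("group", "mouse"), group = c("group", "mouse"))
  # fov ids are needed even when summarising higher, since percentages are
  # always formed per fov first
  needed <- union(needed, c("group", "mouse", "fov"))
  for (col in needed) {
    if (!col %in% names(metrics) || anyNA(metrics[[col]])) {
      bad <- if (col %in% names(metrics)) {
        paste(head(metrics$track_id[is.na(metrics[[col]])], 5), collapse = ", ")
      } else "all"
      abort(sprintf("Metadata column '%s' missing or incomplete (tracks: %s).",
                    col, bad),
            class = "ivtrack_validation_error")
    }
  }
  metrics <- classify_tracks(metrics, th)

  fov_tbl <- metrics |>
    dplyr::group_by(.data$group, .data$mouse, .data$fov) |>
    dplyr::summarise(
      pct_Q1 = 100 * mean(.data$quadrant == "Q1"),
      pct_Q2 = 100 * mean(.data$quadrant == "Q2"),
      pct_Q3 = 100 * mean(.data$quadrant == "Q3"),
      pct_Q4 = 100 * mean(.data$quadrant == "Q4"),
      median_velocity = median(.data$mean_velocity),
      n_tracks = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(motile_pct = .data$pct_Q3 + .data$pct_Q4)
  if (level == "fov") return(fov_tbl)

  mouse_tbl <- fov_tbl |>
    dplyr::group_by(.data$group, .data$mouse) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("pct_Q"), mean),
                     motile_pct = mean(.data$motile_pct),
                     n_tracks = sum(.data$n_tracks),
                     n_fov = dplyr::n(), .groups = "drop")
  mouse_med <- metrics |>
    dplyr::group_by(.data$group, .data$mouse) |>
    dplyr::summarise(median_velocity = median(.data$mean_velocity), .groups = "drop")
  mouse_tbl <- dplyr::left_join(mouse_tbl, mouse_med, by = c("group", "mouse"))
  if (level == "mouse") return(mouse_tbl)

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  mouse_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      dplyr::across(c(dplyr::starts_with("pct_Q"), "motile_pct"),
                    list(mean = mean, sem = sem),
                    .names = "{.fn}_{.col}"),
      n_mice = dplyr::n(),
      n_tracks = sum(.data$n_tracks), .groups = "drop")
}

#' Cell density in cells per cubic millimetre
#'
#' Converts cell counts in one or more sampled tissue regions to a density,
#' averaging the per-region densities: `mean(count / volume) * 1e9`
#' (1 mm^3 = 1e9 um^3).
#'
#' @param counts Non-negative integer cell count per region.
#' @param region_volume_um3 Region volume(s) in cubic micrometres; a scalar
#'   is recycled over regions.
#' @return Density in cells/mm^3.
#' @export
#' @examples
#' cell_density(9, 300 * 300 * 100)  # 1000 cells/mm^3
cell_density <- function(counts, region_volume_um3) {
  if (any(!is.finite(region_volume_um3)) || any(region_volume_um3 <= 0)) {
    abort("Region volumes must be positive.", class = "ivtrack_config_error")
  }
  if (any(counts < 0)) {
    abort("Cell counts must be non-negative.", class = "ivtrack_validation_error")
  }
  mean(counts / region_volume_um3) * 1e9
}
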