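#' Build a run configuration
#'
#' A declarative description of one full analysis run, either from track
#' files on disk (`mode = "files"`) or from a synthetic experiment
#' (`mode = "synthetic"`). All analysis parameters default to the standard
#' study values — 2 um/min velocity threshold, 0.2 confinement threshold,
#' 150 x 150 um collagen crop, 60 um measurement depth, alpha 0.05 — and
#' every default in force is logged when the run starts.
#'
#' @param mode `"synthetic"` or `"files"` (exactly one input mode).
#' @param synthetic A [synthetic_config()] (synthetic mode).
#' @param tracks_path Path to a long-format track CSV (files mode).
#' @param thresholds A [thresholds()] object.
#' @param min_points,min_duration Track filters (see [metrics_table()]).
#' @param comparisons List of length-2 character vectors of group labels to
#'   compare (Mann-Whitney on cell velocities plus per-quadrant
#'   Holm-Sidak-corrected Welch t tests); `NULL` compares nothing.
#' @param kruskal If `TRUE` and there are >= 3 groups, run Kruskal-Wallis
#'   with Dunn's post hoc on velocities across all groups.
#' @param shg_tasks List of SHG tasks; each task is a list with either
#'   `fill_fraction` (synthetic stack) or `path` (TIFF), plus optional
#'   `crop_origin_um`, `crop_size_um`, `plane`, `depth_um`, `y_um`,
#'   `method`, `threshold`, `seed`, `voxel_size_um`.
#' @param alpha Significance level.
#' @param output_dir Directory for tables and the JSON report, or `NULL`
#'   to return the report only.
#' @param seed Root seed (synthetic mode reseeds its config with it).
#' @param verbose Emit one log line per stage.
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("synthetic", "files"), synthetic = NULL,
                       tracks_path = NULL, thresholds = ivtrack::thresholds(),
                       min_points = 5, min_duration = 5, comparisons = NULL,
                       kruskal = FALSE, shg_tasks = list(), alpha = 0.05,
                       output_dir = NULL, seed = 1, verbose = TRUE) {
  cfg <- structure(list(mode = match.arg(mode), synthetic = synthetic,
                        tracks_path = tracks_path, thresholds = thresholds,
                        min_points = min_points, min_duration = min_duration,
                        comparisons = comparisons, kruskal = kruskal,
                        shg_tasks = shg_tasks, alpha = alpha,
                        output_dir = output_dir, seed = as.integer(seed),
                        verbose = isTRUE(verbose)),
                   class = "run_config")
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments
#' (`synthetic` given as a nested map of [synthetic_config()] arguments,
#' with per-group phenotype weights under `groups`).
#'
#' @param path YAML file path.
#' @return A `run_config` object (not yet validated; see
#'   [validate_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: '%s'", path), class = "ivtrack_config_error")
  }
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) abort(sprintf("Cannot parse '%s': %s", path,
                                                  conditionMessage(e)),
                                          class = "ivtrack_config_error"))
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    groups <- if (!is.null(s$groups)) lapply(s$groups, function(w) unlist(w)) else NULL
    geom_args <- s$geometry %||% list()
    syn <- synthetic_config(groups = groups,
                            n_tracks = s$n_tracks %||% 20,
                            n_fov = s$n_fov %||% 3,
                            n_mice = s$n_mice %||% 3,
                            n_follicles = s$n_follicles %||% 3,
                            geometry = do.call(imaging_geometry, geom_args),
                            duration_min = s$duration_min %||% 30,
                            seed = s$seed %||% y$seed %||% 1)
  }
  th <- thresholds(velocity = y$thresholds$velocity %||% 2,
                   confinement = y$thresholds$confinement %||% 0.2)
  run_config(mode = y$mode %||% "synthetic", synthetic = syn,
             tracks_path = y$tracks_path,
             thresholds = th,
             min_points = y$min_points %||% 5,
             min_duration = y$min_duration %||% 5,
             comparisons = y$comparisons,
             kruskal = isTRUE(y$kruskal),
             shg_tasks = y$shg_tasks %||% list(),
             alpha = y$alpha %||% 0.05,
             output_dir = y$output_dir,
             seed = y$seed %||% 1,
             verbose = !isFALSE(y$verbose))
}

#' Validate a run configuration
#'
#' Collects every violation at once rather than stopping at the first.
#'
#' @param config A `run_config` (or a YAML path, which is loaded first).
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "run_config")) {
    return("Not a run_config object.")
  }
  if (!config$mode %in% c("synthetic", "files")) {
    add(sprintf("mode: '%s' is not 'synthetic' or 'files'.", config$mode))
  }
  if (config$mode == "synthetic") {
    if (is.null(config$synthetic)) {
      add("synthetic: mode 'synthetic' requires a synthetic_config.")
    } else if (!inherits(config$synthetic, "synthetic_config")) {
      add("synthetic: not a synthetic_config object.")
    } else if (length(config$synthetic$groups) == 0) {
      add("synthetic$groups: at least one group is required.")
    }
    if (!is.null(config$tracks_path)) {
      add("tracks_path: both input modes set; synthetic mode must not name track files.")
    }
  } else {
    if (is.null(config$tracks_path)) {
      add("tracks_path: mode 'files' requires a track file path.")
    } else if (!file.exists(config$tracks_path)) {
      add(sprintf("tracks_path: file not found: '%s'.", config$tracks_path))
    }
    if (!is.null(config$synthetic)) {
      add("synthetic: both input modes set; files mode must not carry a synthetic_config.")
    }
  }
  th <- config$thresholds
  if (!inherits(th, "thresholds")) {
    add("thresholds: not a thresholds object.")
  }
  if (config$min_points < 0) add("min_points: must be >= 0.")
  if (config$min_duration < 0) add("min_duration: must be >= 0.")
  if (config$alpha <= 0 || config$alpha >= 1) add("alpha: must lie in (0, 1).")
  known_groups <- if (config$mode == "synthetic" &&
                      inherits(config$synthetic, "synthetic_config")) {
    names(config$synthetic$groups)
  } else NULL
  for (cmp in config$comparisons) {
    if (length(cmp) != 2) {
      add(sprintf("comparisons: '%s' is not a pair of group labels.",
                  paste(cmp, collapse = ", ")))
    } else if (!is.null(known_groups) && !all(cmp %in% known_groups)) {
      add(sprintf("comparisons: unknown group(s) in '%s vs %s'.", cmp[1], cmp[2]))
    }
  }
  for (i in seq_along(config$shg_tasks)) {
    task <- config$shg_tasks[[i]]
    has_fill <- !is.null(task$fill_fraction)
    has_path <- !is.null(task$path)
    if (has_fill == has_path) {
      add(sprintf("shg_tasks[%d]: exactly one of fill_fraction or path is required.", i))
    }
    if (has_fill && (task$fill_fraction < 0 || task$fill_fraction > 1)) {
      add(sprintf("shg_tasks[%d]: fill_fraction must lie in [0, 1].", i))
    }
  }
  v
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) inform(sprintf(paste0("[ivtrack] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ingest or simulate tracks, per-track
#' metrics, quadrant classification and hierarchical summaries, group
#' statistics, collagen (SHG) quantification — and assembles a
#' machine-readable report. A failing SHG task is recorded and does not
#' abort the track analysis. Synthetic-mode runs are deterministic given
#' the seed: rerunning the same config reproduces every numeric table
#' byte-identically.
#'
#' @param config A `run_config` from [run_config()] or [read_run_config()].
#' @return A `run_report` list: `per_track`, `per_fov`, `per_mouse`,
#'   `per_group`, `rejections`, `stats` (tibble), `quadrant_stats`,
#'   `shg` (tibble), `shg_errors`, `provenance`. Written to
#'   `config$output_dir` as CSVs plus `report.json` when set.
#' @export
run <- function(config) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    abort(paste0("Invalid run configuration:\n",
                 paste("-", violations, collapse = "\n")),
          class = "ivtrack_config_error")
  }
  vb <- config$verbose
  th <- config$thresholds
  log_stage(vb, "thresholds: velocity %g um/min, confinement %g; filters: >= %g points, >= %g min; alpha %g",
            th$velocity, th$confinement, config$min_points, config$min_duration,
            config$alpha)

  # --- stage 1: ingest or simulate -----------------------------------------
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    syn$seed <- config$seed
    tracks <- simulate_cohort(syn)
    log_stage(vb, "simulate: %d groups, %d tracks, seed %d",
              length(syn$groups), length(unique(tracks$track_id)), config$seed)
  } else {
    tracks <- read_tracks(config$tracks_path, dialect = "long_csv")
    log_stage(vb, "ingest: %d tracks from '%s'",
              length(unique(tracks$track_id)), config$tracks_path)
  }

  # --- stage 2: metrics -----------------------------------------------------
  metrics <- metrics_table(tracks, min_points = config$min_points,
                           min_duration = config$min_duration)
  rej <- rejections(metrics)
  if ("phenotype" %in% names(tracks)) {
    ph <- dplyr::distinct(tracks[, c("track_id", "phenotype")])
    metrics <- dplyr::left_join(metrics, ph, by = "track_id")
  }
  log_stage(vb, "metrics: %d tracks measured, %d rejected", nrow(metrics), nrow(rej))

  # --- stage 3: behaviour ---------------------------------------------------
  metrics <- classify_tracks(metrics, th)
  has_hierarchy <- all(c("group", "mouse", "fov") %in% names(metrics)) &&
    !anyNA(metrics$group) && !anyNA(metrics$mouse) && !anyNA(metrics$fov)
  per_fov <- per_mouse <- per_group <- NULL
  if (has_hierarchy) {
    per_fov <- summarize_behaviour(metrics, th, level = "fov")
    per_mouse <- summarize_behaviour(metrics, th, level = "mouse")
    per_group <- summarize_behaviour(metrics, th, level = "group")
    log_stage(vb, "behaviour: %d fovs, %d mice, %d groups",
              nrow(per_fov), nrow(per_mouse), nrow(per_group))
  } else {
    log_stage(vb, "behaviour: no complete group/mouse/fov metadata, skipping summaries")
  }

  # --- stage 4: statistics --------------------------------------------------
  stat_rows <- list()
  quadrant_stats <- NULL
  for (cmp in config$comparisons) {
    a <- metrics$mean_velocity[metrics$group == cmp[1]]
    b <- metrics$mean_velocity[metrics$group == cmp[2]]
    mw <- mann_whitney(a, b)
    stat_rows[[paste(cmp[1], "vs", cmp[2], "(velocity)")]] <- mw
    if (has_hierarchy) {
      qt <- quadrant_tests(per_mouse, cmp[1], cmp[2], alpha = config$alpha)
      qt$comparison <- paste(cmp[1], "vs", cmp[2])
      quadrant_stats <- dplyr::bind_rows(quadrant_stats, qt)
    }
  }
  dunn <- NULL
  if (isTRUE(config$kruskal)) {
    gs <- split(metrics$mean_velocity, metrics$group)
    if (length(gs) >= 3) {
      kw <- kruskal_wallis(gs)
      stat_rows[["all groups (velocity, Kruskal-Wallis)"]] <- kw
      dunn <- dunn_posthoc(gs, alpha = config$alpha)
    } else {
      log_stage(vb, "stats: kruskal requested but < 3 groups, skipped")
    }
  }
  stats_tbl <- if (length(stat_rows) > 0) tidy_tests(stat_rows) else NULL
  log_stage(vb, "stats: %d two-group tests, %d quadrant rows",
            length(stat_rows), if (is.null(quadrant_stats)) 0 else nrow(quadrant_stats))

  # --- stage 5: collagen ----------------------------------------------------
  shg_rows <- NULL
  shg_errors <- character(0)
  for (i in seq_along(config$shg_tasks)) {
    task <- config$shg_tasks[[i]]
    res <- tryCatch({
      stack <- if (!is.null(task$fill_fraction)) {
        simulate_shg_stack(task$fill_fraction,
                           seed = task$seed %||% seed_child(config$seed, 7919, i))$stack
      } else {
        read_shg_tiff(task$path,
                      voxel_size_um = task$voxel_size_um %||% c(2, 1, 1))
      }
      # default measurement depth: 60 um below the surface, clamped to the
      # deepest plane the stack actually has
      max_depth <- (dim(stack$data)[1] - stack$surface_z) * stack$voxel_size_um[1]
      row <- shg_quantify(stack,
                          plane = task$plane %||% "xy",
                          depth_um = task$depth_um %||% min(60, max_depth),
                          y_um = task$y_um,
                          crop_origin_um = task$crop_origin_um %||% c(0, 0),
                          crop_size_um = task$crop_size_um %||% c(150, 150),
                          method = task$method %||% "otsu",
                          threshold = task$threshold)
      row$task <- i
      row
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      shg_errors <- c(shg_errors, sprintf("task %d: %s", i, res))
    } else {
      shg_rows <- dplyr::bind_rows(shg_rows, res)
    }
  }
  log_stage(vb, "shg: %d of %d tasks completed",
            if (is.null(shg_rows)) 0 else nrow(shg_rows), length(config$shg_tasks))

  report <- structure(list(
    per_track = metrics,
    rejections = rej,
    per_fov = per_fov,
    per_mouse = per_mouse,
    per_group = per_group,
    stats = stats_tbl,
    quadrant_stats = quadrant_stats,
    dunn = dunn,
    shg = shg_rows,
    shg_errors = shg_errors,
    provenance = list(
      config_hash = content_hash(deparse(config[setdiff(names(config), "verbose")])),
      seed = config$seed,
      mode = config$mode,
      package_version = as.character(utils::packageVersion("ivtrack")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a run report to disk
#'
#' Writes every table of a `run_report` as CSV plus a `report.json`
#' carrying the statistics and provenance. Numeric tables depend only on
#' (config, seed); the timestamp lives in the JSON provenance block, so the
#' CSVs of two identical synthetic runs are byte-identical.
#'
#' @param report A `run_report` from [run()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("per_track", "rejections", "per_fov", "per_mouse", "per_group",
              "stats", "quadrant_stats", "dunn", "shg")
  for (nm in tables) {
    if (!is.null(report[[nm]])) {
      tb <- report[[nm]]
      attr(tb, "rejections") <- NULL
      readr::write_csv(tb, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
    }
  }
  json <- list(provenance = report$provenance,
               shg_errors = report$shg_errors,
               n_tracks = nrow(report$per_track),
               n_rejected = nrow(report$rejections))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d tracks (%d rejected)", nrow(x$per_track),
              nrow(x$rejections)))
  if (!is.null(x$per_group)) cat(sprintf(", %d groups", nrow(x$per_group)))
  if (!is.null(x$stats)) cat(sprintf(", %d tests", nrow(x$stats)))
  if (!is.null(x$shg)) cat(sprintf(", %d SHG results", nrow(x$shg)))
  cat(sprintf("\nseed %d, config %s\n", x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}
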