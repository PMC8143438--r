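#' Behavioural phenotype parameters
#'
#' Generative parameters of one migratory phenotype for the persistent
#' random-walk simulator. Cells switch between a paused and a running state
#' by a two-state Markov chain (`pause_prob`: run -> pause per frame;
#' `resume_prob`: pause -> run). While running, the step direction is the
#' previous direction blended with a fresh random unit vector by
#' `persistence` (1 = ballistic, 0 = uncorrelated), and the step length is
#' `max(0, Normal(speed_mean, speed_sd))` scaled to the frame interval.
#' `confinement_radius`, if set, adds a harmonic pull toward an anchor point
#' (a hair-follicle proxy) whose spring constant is chosen so the stationary
#' RMS distance from the anchor is about a third of the radius, making
#' excursions beyond the radius mean-reverting. Finally, Gaussian
#' localization jitter of SD `noise_sd` per coordinate is added to each
#' recorded position.
#'
#' @param name One of `"static"`, `"intermittent"`, `"continuous"`,
#'   `"fast_confined"` (or any label for custom phenotypes).
#' @param speed_mean,speed_sd Run speed distribution, um/min.
#' @param persistence Directional correlation per step, in \[0, 1\].
#' @param pause_prob,resume_prob Per-frame switch probabilities, in \[0, 1\].
#' @param confinement_radius Anchor radius in um, or `NA` for none.
#' @param noise_sd Localization jitter SD per coordinate, um.
#' @return A `phenotype_params` object.
#' @seealso [default_phenotypes()], [simulate_track()]
#' @export
phenotype_params <- function(name, speed_mean, speed_sd = 0, persistence = 0,
                             pause_prob = 0, resume_prob = 1,
                             confinement_radius = NA_real_, noise_sd = 0) {
  probs <- c(pause_prob, resume_prob, persistence)
  if (any(probs < 0) || any(probs > 1)) {
    abort("persistence, pause_prob and resume_prob must lie in [0, 1].",
          class = "ivtrack_config_error")
  }
  if (speed_mean < 0 || speed_sd < 0 || noise_sd < 0) {
    abort("Speeds and noise SD must be non-negative.", class = "ivtrack_config_error")
  }
  if (!is.na(confinement_radius) && confinement_radius <= 0) {
    abort("confinement_radius must be positive (or NA).", class = "ivtrack_config_error")
  }
  structure(list(name = name, speed_mean = speed_mean, speed_sd = speed_sd,
                 persistence = persistence, pause_prob = pause_prob,
                 resume_prob = resume_prob, confinement_radius = confinement_radius,
                 noise_sd = noise_sd),
            class = "phenotype_params")
}

#' Default phenotype library
#'
#' The four canonical phenotypes, parameterised so each lands in its
#' designed behavioural quadrant under the default 60-s / 31-frame
#' acquisition:
#'
#' * `static` (Q1): never runs; only localization jitter.
#' * `intermittent` (Q2/Q1): runs at 4 um/min but pauses often
#'   (pause 0.5, resume 0.3 per frame), keeping the average below the
#'   2 um/min motility line.
#' * `continuous` (Q3): sustained persistent motion at 4 um/min.
#' * `fast_confined` (Q4): fast (6 um/min) but tethered to an anchor with a
#'   25-um confinement radius, well within the ~50-um neighbourhoods of
#'   hair follicles where confined cells orbit, so net displacement — and
#'   hence the confinement ratio — stays low.
#'
#' @return Named list of [phenotype_params()].
#' @export
default_phenotypes <- function() {
  list(
    static = phenotype_params("static", speed_mean = 0, pause_prob = 1,
                              resume_prob = 0, noise_sd = 0.2),
    intermittent = phenotype_params("intermittent", speed_mean = 4, speed_sd = 1,
                                    persistence = 0.6, pause_prob = 0.5,
                                    resume_prob = 0.3, noise_sd = 0.2),
    continuous = phenotype_params("continuous", speed_mean = 4, speed_sd = 1,
                                  persistence = 0.9, noise_sd = 0.2),
    fast_confined = phenotype_params("fast_confined", speed_mean = 6, speed_sd = 1,
                                     persistence = 0.5, confinement_radius = 25,
                                     noise_sd = 0.2))
}

random_unit3 <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Simulate one cell track
#'
#' Generates a discrete-time persistent random walk for one cell, fully
#' reproducible from `seed`: pause/run switching, persistent step
#' directions, optionally a harmonic anchor pull (see [phenotype_params()]),
#' localization jitter, and reflection at the imaging-volume boundaries.
#' Recorded positions are clamped inside the volume.
#'
#' @param phenotype A [phenotype_params()].
#' @param geometry An [imaging_geometry()].
#' @param n_frames Number of recorded frames (default 31: a 30-min recording
#'   at 60-s intervals).
#' @param anchor Length-3 `(x, y, z)` anchor in um; required when the
#'   phenotype has a confinement radius. Ignored otherwise.
#' @param start Length-3 start position, or `NULL` to draw one (uniform in
#'   the volume, or near the anchor for confined phenotypes).
#' @param seed Integer seed for this track's private random stream.
#' @param track_id Identifier for the output rows.
#' @return A long-format track table with `n_frames` rows.
#' @export
simulate_track <- function(phenotype, geometry = imaging_geometry(),
                           n_frames = 31, anchor = NULL, start = NULL,
                           seed = 1, track_id = "sim") {
  stopifnot(inherits(phenotype, "phenotype_params"),
            inherits(geometry, "imaging_geometry"))
  if (n_frames < 2) {
    abort("A track needs at least 2 frames.", class = "ivtrack_config_error")
  }
  confined <- !is.na(phenotype$confinement_radius)
  if (confined && is.null(anchor)) {
    abort("A confined phenotype needs an anchor point.", class = "ivtrack_config_error")
  }
  lim <- c(geometry$field_x, geometry$field_y, geometry$depth)
  dt_min <- geometry$frame_interval / 60
  withr::with_seed(seed, {
    if (is.null(start)) {
      start <- if (confined) {
        pmin(pmax(anchor + random_unit3() * runif(1, 0, phenotype$confinement_radius / 2),
                  0), lim)
      } else {
        runif(3, 0, lim)
      }
    }
    # spring constant: stationary RMS about radius/3 for the given step size
    k <- 0
    if (confined) {
      step_um <- max(phenotype$speed_mean * dt_min, 1e-6)
      k <- min(0.9, 0.5 * (3 * step_um / phenotype$confinement_radius)^2)
    }
    # start the pause/run chain at its stationary distribution
    denom <- phenotype$pause_prob + phenotype$resume_prob
    p_run <- if (denom > 0) phenotype$resume_prob / denom else 1
    running <- runif(1) < p_run
    pos <- start
    dir <- random_unit3()
    true_pos <- matrix(0, n_frames, 3)
    true_pos[1, ] <- pos
    for (f in 2:n_frames) {
      running <- if (running) runif(1) >= phenotype$pause_prob else
        runif(1) < phenotype$resume_prob
      step <- c(0, 0, 0)
      if (running && phenotype$speed_mean + phenotype$speed_sd > 0) {
        dir <- phenotype$persistence * dir +
          (1 - phenotype$persistence) * random_unit3()
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-12) dir <- random_unit3() else dir <- dir / nrm
        len <- max(0, rnorm(1, phenotype$speed_mean, phenotype$speed_sd)) * dt_min
        step <- dir * len
      }
      pos <- pos + step
      if (confined) pos <- pos - k * (pos - anchor)
      # reflect at the volume boundaries
      for (a in 1:3) {
        if (pos[a] < 0) pos[a] <- -pos[a]
        if (pos[a] > lim[a]) pos[a] <- 2 * lim[a] - pos[a]
        pos[a] <- min(max(pos[a], 0), lim[a])
      }
      true_pos[f, ] <- pos
    }
    obs <- true_pos + matrix(rnorm(3 * n_frames, 0, phenotype$noise_sd), n_frames, 3)
    obs <- pmin(pmax(obs, 0), matrix(lim, n_frames, 3, byrow = TRUE))
    tibble::tibble(track_id = track_id,
                   frame = 0:(n_frames - 1),
                   t_s = (0:(n_frames - 1)) * geometry$frame_interval,
                   x_um = obs[, 1], y_um = obs[, 2], z_um = obs[, 3])
  })
}

#' Configuration of a synthetic intravital experiment
#'
#' Describes a full simulated experiment: acquisition geometry, recording
#' duration, the behavioural phenotype mixture per treatment group, and the
#' experimental hierarchy (mice per group, fields of view per mouse, tracks
#' per fov). Defaults mirror a typical skin imaging study: 30-min
#' recordings at 60-s intervals (31 frames) and 3 fovs per mouse.
#'
#' @param groups Named list of mixture weight vectors, one per treatment
#'   group; each weight vector is named by phenotype and must be
#'   non-negative, summing to 1. Default: one group `"A"` with equal
#'   weights over the four default phenotypes.
#' @param phenotypes Named list of [phenotype_params()]
#'   (default [default_phenotypes()]).
#' @param n_tracks Tracks per field of view.
#' @param n_fov Fields of view per mouse (default 3).
#' @param n_mice Mice per group (default 3).
#' @param n_follicles Follicle anchor points placed uniformly per fov, or a
#'   list of fixed `(x, y, z)` anchors used for every fov.
#' @param geometry An [imaging_geometry()].
#' @param duration_min Recording duration in minutes (default 30).
#' @param seed Root seed; every track derives its own stream from it, so
#'   enlarging the cohort never perturbs previously generated tracks.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(groups = NULL, phenotypes = default_phenotypes(),
                             n_tracks = 20, n_fov = 3, n_mice = 3,
                             n_follicles = 3, geometry = imaging_geometry(),
                             duration_min = 30, seed = 1) {
  if (is.null(groups)) {
    w <- rep(1 / length(phenotypes), length(phenotypes))
    groups <- list(A = setNames(w, names(phenotypes)))
  }
  for (g in names(groups)) {
    w <- groups[[g]]
    if (is.null(names(w)) || !all(names(w) %in% names(phenotypes))) {
      abort(sprintf("Group '%s': weights must be named by known phenotypes.", g),
            class = "ivtrack_config_error")
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      abort(sprintf("Group '%s': weights must be non-negative and sum to 1.", g),
            class = "ivtrack_config_error")
    }
  }
  if (n_tracks < 1 || n_fov < 1 || n_mice < 1) {
    abort("n_tracks, n_fov and n_mice must be >= 1.", class = "ivtrack_config_error")
  }
  n_frames <- as.integer(round(duration_min * 60 / geometry$frame_interval)) + 1L
  structure(list(groups = groups, phenotypes = phenotypes, n_tracks = n_tracks,
                 n_fov = n_fov, n_mice = n_mice, n_follicles = n_follicles,
                 geometry = geometry, duration_min = duration_min,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a cohort of tracks
#'
#' Hierarchically samples a full experiment (groups -> mice -> fovs ->
#' tracks) from a [synthetic_config()]. Each track carries `mouse`, `fov`
#' and `group` metadata and its ground-truth `phenotype` label. All
#' randomness derives from per-track child seeds computed from the root
#' seed and the track's position in the hierarchy, so the output is
#' deterministic and stable under cohort growth.
#'
#' @param config A [synthetic_config()].
#' @return A long-format track table with metadata and a `phenotype`
#'   ground-truth column.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pieces <- list()
  i <- 0
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    w <- config$groups[[gi]]
    for (mi in seq_len(config$n_mice)) {
      for (fi in seq_len(config$n_fov)) {
        anchors <- fov_anchors(config, gi, mi, fi)
        for (ti in seq_len(config$n_tracks)) {
          child <- seed_child(config$seed, gi, mi, fi, ti)
          ph_name <- withr::with_seed(seed_child(child, 1), {
            sample(names(w), 1, prob = w)
          })
          ph <- config$phenotypes[[ph_name]]
          anchor <- if (!is.na(ph$confinement_radius)) {
            anchors[[withr::with_seed(seed_child(child, 2),
                                      sample.int(length(anchors), 1))]]
          } else NULL
          id <- sprintf("%s_m%d_f%d_t%03d", gname, mi, fi, ti)
          tr <- simulate_track(ph, config$geometry, config$n_frames,
                               anchor = anchor, seed = seed_child(child, 3),
                               track_id = id)
          tr$mouse <- sprintf("%s_m%d", gname, mi)
          tr$fov <- sprintf("f%d", fi)
          tr$group <- gname
          tr$phenotype <- ph_name
          i <- i + 1
          pieces[[i]] <- tr
        }
      }
    }
  }
  dplyr::bind_rows(pieces)
}

fov_anchors <- function(config, gi, mi, fi) {
  nf <- config$n_follicles
  if (is.list(nf)) return(nf)
  lim <- c(config$geometry$field_x, config$geometry$field_y, config$geometry$depth)
  withr::with_seed(seed_child(config$seed, 104729, gi, mi, fi), {
    lapply(seq_len(nf), function(i) runif(3, c(0, 0, 0), lim))
  })
}
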