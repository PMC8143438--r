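#' Imaging geometry of an intravital recording
#'
#' Physical description of one imaged volume: lateral field size, imaging
#' depth, z step and frame interval. Defaults follow a typical multiphoton
#' skin acquisition: volumes to 100 um depth at 2 um z step, one stack every
#' 60 s. The lateral field defaults to 300 x 300 um, a realistic dermal field
#' for a 25x objective; it is a property of the synthetic experiment, not a
#' calibration of any particular microscope.
#'
#' @param field_x,field_y Lateral field size in micrometres.
#' @param depth Imaging depth in micrometres (sanity-bounded to [1, 1000]).
#' @param frame_interval Time between volumes, seconds.
#' @param z_step Axial step between planes, micrometres.
#' @return An object of class `imaging_geometry` (a named list).
#' @export
#' @examples
#' imaging_geometry(depth = 150)
imaging_geometry <- function(field_x = 300, field_y = 300, depth = 100,
                             frame_interval = 60, z_step = 2) {
  vals <- c(field_x = field_x, field_y = field_y, depth = depth,
            frame_interval = frame_interval, z_step = z_step)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("All imaging geometry values must be finite and positive.",
          class = "ivtrack_geometry_error")
  }
  if (depth < 1 || depth > 1000) {
    abort(sprintf("depth = %g um is outside the sanity bound [1, 1000] um.", depth),
          class = "ivtrack_geometry_error")
  }
  structure(as.list(vals), class = "imaging_geometry")
}

#' @export
print.imaging_geometry <- function(x, ...) {
  cat(sprintf(
    "<imaging_geometry> %g x %g um field, %g um depth, %g um z step, %g s frame interval\n",
    x$field_x, x$field_y, x$depth, x$z_step, x$frame_interval))
  invisible(x)
}

#' Derive a child seed from a root seed and indices
#'
#' Deterministic counter-based seed splitting: the child depends only on the
#' root seed and the integer indices, not on call order, so enlarging a
#' simulated cohort never perturbs the streams of existing tracks. The
#' result stays below 2^31, a valid R integer seed. (LCG-style mixing on
#' doubles; all intermediates stay well under 2^53.)
#'
#' @param root Integer root seed.
#' @param ... Integer indices identifying the consumer (e.g. group, mouse,
#'   fov, track).
#' @return An integer seed.
#' @export
seed_child <- function(root, ...) {
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + (k + 1) * 16807 + 12345) %% m
  }
  as.integer(h)
}

# Polynomial rolling hash of a character vector, returned as hex.
# Used for config provenance only (not cryptographic).
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
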