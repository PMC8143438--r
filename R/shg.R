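#' Second-harmonic-generation image stack
#'
#' A grayscale 3D image volume with physical voxel sizes, used for
#' quantifying fibrillar-collagen signal. Intensities are stored as a
#' numeric array with dimensions ordered `(z, y, x)`; voxel sizes are
#' micrometres per voxel along the same axes. `surface_z` is the 1-based
#' plane index of the skin surface (default 1, the first acquired plane),
#' the reference from which depths "below the surface" are measured.
#'
#' @param data 3D numeric array `(z, y, x)` of non-negative intensities; a
#'   2D matrix is treated as a single plane.
#' @param voxel_size_um Numeric length-3 `(z, y, x)` voxel size in um.
#' @param surface_z 1-based z index of the skin surface.
#' @return An `shg_stack` object.
#' @export
shg_stack <- function(data, voxel_size_um = c(2, 1, 1), surface_z = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(1, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("Stack data must be a (z, y, x) array or a single-plane matrix.",
          class = "ivtrack_validation_error")
  }
  if (any(dim(data) < 1)) {
    abort("All stack dimensions must be >= 1.", class = "ivtrack_validation_error")
  }
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    abort("voxel_size_um must be 3 positive values (z, y, x).",
          class = "ivtrack_validation_error")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    abort("Intensities must be finite and non-negative.",
          class = "ivtrack_validation_error")
  }
  surface_z <- as.integer(surface_z)
  if (surface_z < 1 || surface_z > dim(data)[1]) {
    abort("surface_z must index an existing plane.", class = "ivtrack_validation_error")
  }
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 surface_z = surface_z),
            class = "shg_stack")
}

#' @export
print.shg_stack <- function(x, ...) {
  d <- dim(x$data)
  v <- x$voxel_size_um
  cat(sprintf("<shg_stack> %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um/voxel (%.4g x %.4g x %.4g um), surface at z = %d\n",
              d[1], d[2], d[3], v[1], v[2], v[3],
              d[1] * v[1], d[2] * v[2], d[3] * v[3], x$surface_z))
  invisible(x)
}

#' Crop a lateral region from a stack
#'
#' Extracts a lateral (x, y) sub-region across all z planes, the standard
#' preparation step that restricts collagen quantification to a
#' follicle-free region. The default size is 150 x 150 um. Micrometre
#' coordinates are converted to voxels by flooring the origin and rounding
#' the extent.
#'
#' @param stack An [shg_stack()].
#' @param origin_um Length-2 `(x, y)` origin of the crop in um, measured
#'   from the stack's corner.
#' @param size_um Length-2 `(x, y)` crop size in um (default `c(150, 150)`).
#' @return The cropped `shg_stack`.
#' @export
crop_region <- function(stack, origin_um = c(0, 0), size_um = c(150, 150)) {
  stopifnot(inherits(stack, "shg_stack"))
  d <- dim(stack$data)
  vx <- stack$voxel_size_um[3]; vy <- stack$voxel_size_um[2]
  x0 <- floor(origin_um[1] / vx); y0 <- floor(origin_um[2] / vy)
  nx <- round(size_um[1] / vx);   ny <- round(size_um[2] / vy)
  if (x0 < 0 || y0 < 0 || nx < 1 || ny < 1 || x0 + nx > d[3] || y0 + ny > d[2]) {
    abort(sprintf(
      paste0("Crop out of bounds: requested origin (%g, %g) um / size (%g, %g) um ",
             "= voxels x [%d, %d], y [%d, %d] on a %d x %d (x, y) voxel stack."),
      origin_um[1], origin_um[2], size_um[1], size_um[2],
      x0 + 1, x0 + nx, y0 + 1, y0 + ny, d[3], d[2]),
      class = "ivtrack_bounds_error")
  }
  sub <- stack$data[, (y0 + 1):(y0 + ny), (x0 + 1):(x0 + nx), drop = FALSE]
  shg_stack(sub, stack$voxel_size_um, stack$surface_z)
}

#' Extract a single plane from a stack
#'
#' Returns an `xy` plane at a given depth below the skin surface, or a `zx`
#' cross-section at a given lateral y position. The xy plane index is
#' `surface_z + round(depth / z_step)`; collagen quantification is
#' conventionally reported 60 um below the surface.
#'
#' @param stack An [shg_stack()].
#' @param plane `"xy"` or `"zx"`.
#' @param depth_um Depth below the surface in um (xy planes).
#' @param y_um Lateral y coordinate in um (zx planes).
#' @return A list: `image` (2D matrix, rows = first named axis), and
#'   `pixel_size_um` (length-2, per matrix axis).
#' @export
extract_plane <- function(stack, plane = c("xy", "zx"), depth_um = NULL, y_um = NULL) {
  stopifnot(inherits(stack, "shg_stack"))
  plane <- match.arg(plane)
  d <- dim(stack$data)
  if (plane == "xy") {
    if (is.null(depth_um)) abort("xy plane needs depth_um.", class = "ivtrack_config_error")
    zi <- stack$surface_z + round(depth_um / stack$voxel_size_um[1])
    if (zi < 1 || zi > d[1]) {
      abort(sprintf("Depth %g um maps to plane %d, outside 1..%d.", depth_um, zi, d[1]),
            class = "ivtrack_bounds_error")
    }
    img <- stack$data[zi, , , drop = TRUE]
    dim(img) <- d[2:3]
    list(image = img, pixel_size_um = stack$voxel_size_um[2:3],
         plane = "xy", index = zi)
  } else {
    if (is.null(y_um)) abort("zx plane needs y_um.", class = "ivtrack_config_error")
    yi <- floor(y_um / stack$voxel_size_um[2]) + 1
    if (yi < 1 || yi > d[2]) {
      abort(sprintf("y = %g um maps to row %d, outside 1..%d.", y_um, yi, d[2]),
            class = "ivtrack_bounds_error")
    }
    img <- stack$data[, yi, , drop = TRUE]
    dim(img) <- d[c(1, 3)]
    list(image = img, pixel_size_um = stack$voxel_size_um[c(1, 3)],
         plane = "zx", index = yi)
  }
}

#' Otsu threshold of an image
#'
#' Global intensity threshold maximizing the between-class variance of the
#' image's 256-bin histogram. The returned value is on the original
#' intensity scale; pixels with intensity at or above it are "positive".
#' A constant image has no Otsu threshold; the midpoint of the intensity
#' range (the value itself) is returned with a warning.
#'
#' @param image Numeric matrix or array of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity (scalar).
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  if (length(v) == 0) abort("Empty image.", class = "ivtrack_validation_error")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    warn("Constant image: Otsu threshold undefined, falling back to the midpoint.")
    return(lo)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(v)
  omega <- cumsum(p)                    # class-0 weight up to cut k
  mu <- cumsum(p * seq_len(n_bins))     # class-0 first moment (bin units)
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  # all cuts through an empty inter-mode gap tie exactly; take their midpoint
  k_star <- round(mean(which(sigma_b == max(sigma_b))))
  breaks[k_star + 1]  # boundary: first positive intensity
}

#' Positive-area fraction of an image
#'
#' Percentage of pixels whose intensity is at or above a threshold — the
#' standard "% of area filled by signal" measurement for collagen imaging.
#' The threshold is found by Otsu's method by default, or supplied as a
#' fixed value; either way the value used is recorded in the result.
#'
#' @param image Numeric matrix of intensities (e.g. from [extract_plane()]).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold intensity, required for `method = "fixed"`.
#' @return A one-row tibble: `percent_area`, `threshold_used`, `method`,
#'   `n_pixels`.
#' @export
#' @examples
#' img <- matrix(c(rep(0, 60), rep(255, 40)), 10, 10)
#' area_fraction(img, method = "fixed", threshold = 128)
area_fraction <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  v <- as.numeric(image)
  if (length(v) == 0) abort("Empty image.", class = "ivtrack_validation_error")
  if (method == "otsu") {
    threshold <- otsu_threshold(image)
  } else if (is.null(threshold) || !is.finite(threshold)) {
    abort("method = 'fixed' requires a finite threshold.", class = "ivtrack_config_error")
  }
  tibble::tibble(percent_area = 100 * mean(v >= threshold),
                 threshold_used = threshold,
                 method = method,
                 n_pixels = length(v))
}

#' Mean intensity of an image
#'
#' @param image Numeric matrix or array.
#' @return Arithmetic mean of all pixel intensities.
#' @export
mean_intensity <- function(image) {
  if (length(image) == 0) abort("Empty image.", class = "ivtrack_validation_error")
  mean(as.numeric(image))
}

#' Quantify collagen signal in a stack
#'
#' One-call composition of the standard workflow: crop a follicle-free
#' lateral region (default 150 x 150 um), extract the requested plane
#' (default xy at 60 um below the surface), and measure the positive-area
#' fraction and mean intensity.
#'
#' @inheritParams crop_region
#' @inheritParams extract_plane
#' @inheritParams area_fraction
#' @param crop_origin_um `(x, y)` crop origin in um, or `NULL` to skip
#'   cropping.
#' @param crop_size_um `(x, y)` crop size in um.
#' @return One-row tibble: `plane`, `depth_um`, `percent_area`,
#'   `threshold_used`, `method`, `mean_intensity`, `crop_x_um`, `crop_y_um`,
#'   `crop_w_um`, `crop_h_um`.
#' @export
shg_quantify <- function(stack, plane = "xy", depth_um = 60, y_um = NULL,
                         crop_origin_um = c(0, 0), crop_size_um = c(150, 150),
                         method = "otsu", threshold = NULL) {
  cropped <- if (is.null(crop_origin_um)) stack else
    crop_region(stack, crop_origin_um, crop_size_um)
  pl <- extract_plane(cropped, plane, depth_um = depth_um, y_um = y_um)
  af <- area_fraction(pl$image, method = method, threshold = threshold)
  tibble::tibble(plane = pl$plane,
                 depth_um = if (identical(pl$plane, "xy")) depth_um else NA_real_,
                 percent_area = af$percent_area,
                 threshold_used = af$threshold_used,
                 method = af$method,
                 mean_intensity = mean_intensity(pl$image),
                 crop_x_um = if (is.null(crop_origin_um)) NA_real_ else crop_origin_um[1],
                 crop_y_um = if (is.null(crop_origin_um)) NA_real_ else crop_origin_um[2],
                 crop_w_um = if (is.null(crop_origin_um)) NA_real_ else crop_size_um[1],
                 crop_h_um = if (is.null(crop_origin_um)) NA_real_ else crop_size_um[2])
}

#' Read a grayscale TIFF into an `shg_stack`
#'
#' Reads single- or multi-page grayscale TIFF (8/16-bit unsigned or float).
#' Integer TIFFs are read at their native integer scale. Voxel sizes come
#' from the caller; TIFF metadata is not interpreted.
#'
#' @param path TIFF file path.
#' @inheritParams shg_stack
#' @return An [shg_stack()].
#' @export
read_shg_tiff <- function(path, voxel_size_um = c(2, 1, 1), surface_z = 1) {
  if (!file.exists(path)) {
    abort(sprintf("TIFF not found: '%s'", path), class = "ivtrack_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale-with-channels
    p
  })
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  shg_stack(arr, voxel_size_um, surface_z)
}

#' Write an `shg_stack` as a multi-page 16-bit TIFF
#'
#' Intensities must lie in \[0, 65535\]; they are stored as 16-bit unsigned
#' samples (fractional values are rounded on write).
#'
#' @param stack An [shg_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shg_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "shg_stack"))
  if (max(stack$data) > 65535) {
    abort("Intensities exceed the 16-bit range.", class = "ivtrack_io_error")
  }
  pages <- lapply(seq_len(dim(stack$data)[1]), function(i) {
    m <- stack$data[i, , , drop = TRUE]
    dim(m) <- dim(stack$data)[2:3]
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
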