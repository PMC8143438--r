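mk_stack <- function(nz = 4, ny = 20, nx = 20, value = 0, vox = c(2, 1, 1)) {
  shg_stack(array(value, c(nz, ny, nx)), voxel_size_um = vox)
}

test_that("cropping converts micrometres to voxels and checks bounds", {
  st <- mk_stack(nz = 2, ny = 300, nx = 300, vox = c(2, 1, 1))
  st$data[1, 100, 100] <- 9  # inside a (75,75)+150 crop
  cr <- crop_region(st, origin_um = c(75, 75), size_um = c(150, 150))
  expect_equal(dim(cr$data), c(2, 150, 150))
  expect_equal(cr$data[1, 100 - 75, 100 - 75], 9)

  # crop equal to the full extent is the identity
  full <- crop_region(st, origin_um = c(0, 0), size_um = c(300, 300))
  expect_equal(full$data, st$data)

  err <- expect_error(crop_region(st, origin_um = c(200, 200),
                                  size_um = c(150, 150)),
                      class = "ivtrack_bounds_error")
  expect_match(conditionMessage(err), "um")
  expect_match(conditionMessage(err), "voxel")
})

test_that("plane extraction maps depth below surface to the expected index", {
  st <- mk_stack(nz = 40, ny = 8, nx = 8, vox = c(2, 1, 1))
  st$data[31, 3, 5] <- 1  # 60 um below a surface at the first plane
  pl <- extract_plane(st, "xy", depth_um = 60)
  expect_equal(pl$index, 31)
  expect_equal(pl$image[3, 5], 1)

  surf <- extract_plane(st, "xy", depth_um = 0)
  expect_equal(surf$index, 1)

  expect_error(extract_plane(st, "xy", depth_um = 500),
               class = "ivtrack_bounds_error")
})

test_that("zx extraction picks the requested y slice with (z, x) layout", {
  st <- mk_stack(nz = 6, ny = 10, nx = 12, vox = c(2, 1, 1))
  st$data[5, 7, 9] <- 42
  pl <- extract_plane(st, "zx", y_um = 6.5)  # voxel row 7
  expect_equal(pl$index, 7)
  expect_equal(pl$image[5, 9], 42)
  expect_equal(dim(pl$image), c(6, 12))
  expect_equal(pl$pixel_size_um, c(2, 1))
})

test_that("fixed-threshold area fraction counts pixels at or above the threshold", {
  img <- matrix(0, 10, 10); img[1:40] <- 255
  expect_equal(area_fraction(img, "fixed", threshold = 128)$percent_area, 40)
  expect_equal(area_fraction(matrix(0, 5, 5), "fixed", threshold = 1)$percent_area, 0)
  # at-threshold pixels are positive
  img2 <- matrix(c(127, 128), 1, 2)
  expect_equal(area_fraction(img2, "fixed", threshold = 128)$percent_area, 50)
})

test_that("Otsu threshold splits a bimodal image and recovers the mixing fraction", {
  withr::with_seed(11, {
    img <- matrix(c(rnorm(7000, 50, 10), rnorm(3000, 200, 10))[sample(10000)],
                  100, 100)
  })
  # independent oracle: exhaustive search over 256 candidate thresholds for
  # max between-class variance
  v <- as.numeric(img)
  cand <- seq(min(v), max(v), length.out = 256)
  bcv <- vapply(cand, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) / length(v) * length(hi) / length(v) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  oracle_t <- cand[which.max(bcv)]

  t_pkg <- otsu_threshold(img)
  # both must land in the empty inter-mode gap; the gap itself spans tens of
  # intensity units so agreement is asserted coarsely
  expect_gt(t_pkg, max(v[v < 130]))
  expect_lt(t_pkg, min(v[v > 130]))
  expect_lt(abs(t_pkg - oracle_t), 45)

  af <- area_fraction(img, "otsu")
  expect_lt(abs(af$percent_area - 30), 1)
  expect_equal(af$threshold_used, t_pkg)
})

test_that("area fraction is non-increasing in the fixed threshold", {
  withr::with_seed(4, img <- matrix(runif(400, 0, 255), 20, 20))
  ts <- seq(0, 260, by = 20)
  pa <- vapply(ts, function(t) area_fraction(img, "fixed", t)$percent_area,
               numeric(1))
  expect_true(all(diff(pa) <= 0))
})

test_that("Otsu-based area fraction is invariant under increasing remapping of a bimodal image", {
  withr::with_seed(12, {
    img <- matrix(c(rnorm(600, 40, 8), rnorm(400, 180, 8)), 25, 40)
  })
  a0 <- area_fraction(img, "otsu")$percent_area
  a1 <- area_fraction(sqrt(img - min(img) + 1), "otsu")$percent_area
  expect_equal(a0, a1)
})

test_that("constant images fall back to a midpoint threshold with a warning", {
  expect_warning(t0 <- otsu_threshold(matrix(7, 4, 4)), "Constant")
  expect_equal(t0, 7)
  expect_warning(af <- area_fraction(matrix(7, 4, 4), "otsu"), "Constant")
  expect_equal(af$percent_area, 100)  # every pixel sits at the threshold
})

test_that("mean intensity is the plain arithmetic mean", {
  expect_equal(mean_intensity(matrix(7, 3, 3)), 7)
  chk <- matrix(c(0, 10), 8, 8)
  expect_equal(mean_intensity(chk), 5)
  withr::with_seed(2, img <- matrix(runif(100), 10, 10))
  expect_equal(mean_intensity(img), sum(img) / 100)
})

test_that("16-bit TIFF round-trips through read/write", {
  withr::with_seed(8, {
    arr <- array(sample(0:65535, 3 * 6 * 5, replace = TRUE), c(3, 6, 5))
  })
  st <- shg_stack(arr, voxel_size_um = c(2, 1, 1))
  p <- withr::local_tempfile(fileext = ".tif")
  write_shg_tiff(st, p)
  back <- read_shg_tiff(p, voxel_size_um = c(2, 1, 1))
  expect_equal(back$data, st$data)
})

test_that("the composite quantification records crop, plane and threshold provenance", {
  sim <- simulate_shg_stack(0.4, geometry = imaging_geometry(field_x = 60, field_y = 60,
                                                             depth = 10),
                            fibre_length = 20, fibre_thickness = 3, seed = 3)
  res <- shg_quantify(sim$stack, plane = "xy", depth_um = 4,
                      crop_origin_um = c(5, 5), crop_size_um = c(50, 50),
                      method = "fixed", threshold = sim$noise_ceiling + 1)
  expect_equal(res$crop_w_um, 50)
  expect_equal(res$method, "fixed")
  expect_true(res$percent_area >= 0 && res$percent_area <= 100)
})
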