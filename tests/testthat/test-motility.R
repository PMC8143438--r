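test_that("collinear constant-speed track gives textbook metrics", {
  tr <- tibble::tibble(track_id = "a", frame = 0:2, t_s = c(0, 60, 120),
                       x_um = c(0, 3, 6), y_um = 0, z_um = 0)
  m <- metrics_table(tr, min_points = 0, min_duration = 0)
  expect_equal(m$path_length, 6)
  expect_equal(m$displacement, 6)
  expect_equal(m$mean_velocity, 3)
  expect_equal(m$confinement, 1)
  expect_equal(m$duration, 2)
})

test_that("a closed loop has zero displacement and zero confinement", {
  tr <- tibble::tibble(track_id = "loop", frame = 0:4,
                       t_s = seq(0, 240, by = 60),
                       x_um = c(0, 5, 5, 0, 0), y_um = c(0, 0, 5, 5, 0),
                       z_um = 0)
  m <- metrics_table(tr, min_points = 0, min_duration = 0)
  expect_equal(m$displacement, 0)
  expect_equal(m$path_length, 20)
  expect_equal(m$confinement, 0)
})

test_that("metrics agree with the brute-force oracle on random 3D tracks", {
  for (i in 1:20) {
    tr <- random_track(sprintf("r%d", i), n = 31, seed = 400 + i)
    m <- metrics_table(tr, min_points = 0, min_duration = 0)
    o <- oracle_metrics(tr)
    expect_equal(m$path_length, o$path_length, tolerance = 1e-9)
    expect_equal(m$displacement, o$displacement, tolerance = 1e-9)
    expect_equal(m$mean_velocity, o$mean_velocity, tolerance = 1e-9)
    expect_equal(m$confinement, o$confinement, tolerance = 1e-9)
  }
})

test_that("confinement lies in [0,1] and displacement never exceeds path length", {
  for (i in 1:50) {
    tr <- random_track("p", n = sample(3:40, 1), seed = 900 + i)
    m <- metrics_table(tr, min_points = 0, min_duration = 0)
    expect_gte(m$confinement, 0)
    expect_lte(m$confinement, 1)
    expect_lte(m$displacement, m$path_length + 1e-12)
  }
})

test_that("metrics transform correctly under scaling and rigid motion", {
  tr <- random_track("t", n = 25, seed = 7)
  m0 <- metrics_table(tr, 0, 0)

  s <- 3.7
  ms <- metrics_table(apply_affine(tr, scale = s), 0, 0)
  expect_equal(ms$path_length, s * m0$path_length, tolerance = 1e-9)
  expect_equal(ms$displacement, s * m0$displacement, tolerance = 1e-9)
  expect_equal(ms$mean_velocity, s * m0$mean_velocity, tolerance = 1e-9)
  expect_equal(ms$confinement, m0$confinement, tolerance = 1e-9)

  rot <- rotation_matrix(c(1, 2, 3), 1.1)
  mr <- metrics_table(apply_affine(tr, rot = rot, shift = c(50, -20, 5)), 0, 0)
  expect_equal(mr$path_length, m0$path_length, tolerance = 1e-9)
  expect_equal(mr$displacement, m0$displacement, tolerance = 1e-9)
  expect_equal(mr$confinement, m0$confinement, tolerance = 1e-9)
})

test_that("mean confinement of an unbiased random walk decreases with walk length", {
  mean_conf <- function(n_steps, seed0) {
    vals <- vapply(1:500, function(i) {
      withr::with_seed(seed0 + i, {
        # uniform lattice steps along +-x/+-y/+-z
        dirs <- matrix(c(1,0,0, -1,0,0, 0,1,0, 0,-1,0, 0,0,1, 0,0,-1), 6, 3,
                       byrow = TRUE)
        steps <- dirs[sample.int(6, n_steps, replace = TRUE), , drop = FALSE]
        pos <- apply(steps, 2, cumsum)
        path <- n_steps
        disp <- sqrt(sum(pos[n_steps, ]^2))
        disp / path
      })
    }, numeric(1))
    mean(vals)
  }
  expect_lt(mean_conf(100, 10000), mean_conf(9, 20000))
})

test_that("short tracks are rejected with a recorded reason", {
  long <- lapply(1:5, function(i) random_track(sprintf("ok%d", i), n = 10,
                                               seed = 50 + i))
  short <- tibble::tibble(track_id = "tiny", frame = 0:1, t_s = c(0, 60),
                          x_um = c(0, 1), y_um = 0, z_um = 0)
  m <- metrics_table(dplyr::bind_rows(c(long, list(short))),
                     min_points = 5, min_duration = 5)
  expect_equal(nrow(m), 5)
  rej <- rejections(m)
  expect_equal(rej$track_id, "tiny")
  expect_match(rej$reason, "too few points")
})

test_that("empty input and identical tracks behave deterministically", {
  m0 <- metrics_table(tibble::tibble())
  expect_equal(nrow(m0), 0)

  a <- random_track("a", n = 12, seed = 3)
  b <- a; b$track_id <- "b"
  m <- metrics_table(dplyr::bind_rows(a, b), 0, 0)
  expect_equal(m$path_length[1], m$path_length[2])
  expect_equal(m$confinement[1], m$confinement[2])
})

test_that("single-track wrapper returns one row or explains rejection", {
  tr <- random_track("solo", n = 12, seed = 5)
  expect_equal(nrow(track_metrics(tr, 0, 0)), 1)
  short <- tr[1:2, ]
  expect_message(out <- track_metrics(short), "rejected")
  expect_null(out)
})
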