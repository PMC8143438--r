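mk_metrics <- function(v, c, ...) {
  tibble::tibble(track_id = sprintf("t%d", seq_along(v)),
                 mean_velocity = v, confinement = c, ...)
}

test_that("quadrant classification follows the threshold rules, boundaries count as high", {
  m <- mk_metrics(v = c(3.0, 1.0, 2.0, 3.0, 1.0),
                  c = c(0.5, 0.1, 0.2, 0.1, 0.5))
  q <- classify_tracks(m)$quadrant
  expect_equal(as.character(q), c("Q3", "Q1", "Q3", "Q4", "Q2"))
})

test_that("every track gets exactly one quadrant and raising velocity is monotone", {
  withr::with_seed(42, {
    m <- mk_metrics(v = runif(300, 0, 6), c = runif(300))
  })
  cl <- classify_tracks(m)
  expect_false(anyNA(cl$quadrant))
  expect_equal(nrow(cl), 300)
  # raising velocity can only move Q1 -> Q4 or Q2 -> Q3
  m2 <- m; m2$mean_velocity <- m2$mean_velocity + 2.5
  cl2 <- classify_tracks(m2)
  trans <- paste(cl$quadrant, cl2$quadrant)
  expect_true(all(trans %in% c("Q1 Q1", "Q1 Q4", "Q2 Q2", "Q2 Q3",
                               "Q3 Q3", "Q4 Q4")))
})

test_that("motile fraction counts cells at or above the velocity threshold", {
  expect_equal(motile_fraction(mk_metrics(c(1, 1, 3, 3), rep(0.5, 4))), 50)
  expect_equal(motile_fraction(mk_metrics(rep(0, 5), rep(0, 5))), 0)
  expect_error(motile_fraction(mk_metrics(numeric(0), numeric(0))),
               class = "ivtrack_computation_error")
})

test_that("motile fraction of a seeded balanced cohort falls in the exact binomial interval", {
  cfg <- synthetic_config(groups = list(A = c(static = 0.5, continuous = 0.5)),
                          n_tracks = 200, n_fov = 1, n_mice = 1, seed = 314)
  m <- metrics_table(simulate_cohort(cfg), min_points = 0, min_duration = 0)
  est <- motile_fraction(m) / 100
  bounds <- stats::qbinom(c(0.025, 0.975), 200, 0.5) / 200
  expect_gte(est, bounds[1])
  expect_lte(est, bounds[2])
})

test_that("velocity histogram uses half-open bins and matches direct counting", {
  vd <- velocity_distribution(c(0.5, 1.5, 2.5), bin_width = 1)
  expect_equal(vd$histogram$rel_freq, rep(1 / 3, 3))
  expect_equal(vd$histogram$bin_left, c(0, 1, 2))
  expect_equal(vd$median_velocity, 1.5)

  single <- velocity_distribution(2.2, bin_width = 0.5)
  expect_equal(nrow(single$histogram), 1)
  expect_equal(single$histogram$rel_freq, 1)

  withr::with_seed(99, v <- runif(1000, 0, 10))
  vd2 <- velocity_distribution(v, bin_width = 0.5)
  oracle <- vapply(seq_len(nrow(vd2$histogram)), function(i) {
    sum(v >= vd2$histogram$bin_left[i] & v < vd2$histogram$bin_right[i])
  }, numeric(1))
  expect_equal(vd2$histogram$count, oracle)
  expect_equal(sum(vd2$histogram$rel_freq), 1)
  # a value on a bin edge belongs to the right-hand bin
  edge <- velocity_distribution(c(0.999, 1.0), bin_width = 1)
  expect_equal(edge$histogram$count, c(1, 1))
})

test_that("behaviour summaries aggregate fov -> mouse -> group in that order", {
  m1 <- mk_metrics(v = c(1, 1, 3, 3), c = c(0.1, 0.1, 0.5, 0.1),
                   group = "A", mouse = "m1", fov = "f1")
  s1 <- summarize_behaviour(m1, level = "fov")
  expect_equal(unlist(s1[, c("pct_Q1", "pct_Q2", "pct_Q3", "pct_Q4")],
                      use.names = FALSE), c(50, 0, 25, 25))
  expect_equal(s1$motile_pct, 50)

  # two fovs, 100% Q1 and 100% Q3: mouse level averages percentages, not cells
  m2 <- dplyr::bind_rows(
    mk_metrics(v = rep(1, 3), c = rep(0.1, 3), group = "A", mouse = "m1", fov = "f1"),
    mk_metrics(v = rep(3, 9), c = rep(0.5, 9), group = "A", mouse = "m1", fov = "f2"))
  s2 <- summarize_behaviour(m2, level = "mouse")
  expect_equal(unlist(s2[, c("pct_Q1", "pct_Q2", "pct_Q3", "pct_Q4")],
                      use.names = FALSE), c(50, 0, 50, 0))

  # group level equals the mean over mice of mouse-level values
  m3 <- dplyr::bind_rows(m2,
    mk_metrics(v = rep(3, 4), c = rep(0.5, 4), group = "A", mouse = "m2", fov = "f1"))
  s_mouse <- summarize_behaviour(m3, level = "mouse")
  s_group <- summarize_behaviour(m3, level = "group")
  expect_equal(s_group$mean_pct_Q1, mean(s_mouse$pct_Q1))
  expect_equal(s_group$mean_pct_Q3, mean(s_mouse$pct_Q3))
  expect_equal(s_group$sem_pct_Q3, sd(s_mouse$pct_Q3) / sqrt(2))
  expect_equal(s_group$n_mice, 2)

  # missing metadata is an error that names the affected tracks
  m_bad <- mk_metrics(v = c(1, 2), c = c(0.1, 0.1), group = "A",
                      mouse = c("m1", NA), fov = "f1")
  expect_error(summarize_behaviour(m_bad, level = "mouse"), "mouse",
               class = "ivtrack_validation_error")
})

test_that("quadrant percentages sum to 100 and motile equals Q3 + Q4 on random cohorts", {
  cfg <- synthetic_config(n_tracks = 15, n_fov = 2, n_mice = 2, seed = 77)
  m <- metrics_table(simulate_cohort(cfg), min_points = 0, min_duration = 0)
  s <- summarize_behaviour(m, level = "fov")
  sums <- s$pct_Q1 + s$pct_Q2 + s$pct_Q3 + s$pct_Q4
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_equal(s$motile_pct, s$pct_Q3 + s$pct_Q4)
  # the two motile-fraction code paths agree per fov
  for (i in seq_len(nrow(s))) {
    sub <- m[m$fov == s$fov[i] & m$mouse == s$mouse[i], ]
    expect_equal(motile_fraction(sub), s$motile_pct[i], tolerance = 1e-9)
  }
})

test_that("cell density converts counts and volumes to cells per cubic millimetre", {
  expect_equal(cell_density(9, 300 * 300 * 100), 1000)
  expect_equal(cell_density(0, 1e6), 0)
  v <- 5e6
  expect_equal(cell_density(c(10, 20), v), mean(c(10, 20) / v) * 1e9)
  expect_error(cell_density(5, 0), class = "ivtrack_config_error")
})
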