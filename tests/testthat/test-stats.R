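test_that("Mann-Whitney matches the enumeration oracle on small tie-free samples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)

  withr::with_seed(31, {
    for (i in 1:15) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      vals <- sample(100, n1 + n2)  # tie-free
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney is symmetric in its arguments and handles degeneracy", {
  withr::with_seed(5, { x <- rnorm(12); y <- rnorm(9, 1) })
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value,
               tolerance = 1e-12)
  expect_equal(mann_whitney(x, x)$p_value, 1, tolerance = 1e-12)
  expect_warning(res <- mann_whitney(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(res$p_value, 1)
  # ties force the approximation even when exactness is requested
  expect_warning(res2 <- mann_whitney(c(1, 2, 2), c(2, 3, 4), mode = "exact"),
                 "Ties")
  expect_false(res2$exact)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle and handles identical groups", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  # direct rank-sum arithmetic: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  n_all <- 6
  r <- rank(unlist(groups))
  rs <- c(sum(r[1:2]), sum(r[3:4]), sum(r[5:6]))
  h_oracle <- 12 / (n_all * (n_all + 1)) * sum(rs^2 / 2) - 3 * (n_all + 1)
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, h_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)

  expect_warning(same <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1))),
                 "identical")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(list(1:3, 4:6)), class = "ivtrack_validation_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0), 4:6)),
               class = "ivtrack_validation_error")
})

test_that("H is invariant under strictly monotone transforms of the pooled data", {
  withr::with_seed(17, gs <- list(rnorm(8), rnorm(6, 0.5), rnorm(7, 1)))
  h0 <- kruskal_wallis(gs)$statistic
  h1 <- kruskal_wallis(lapply(gs, function(g) exp(3 * g)))$statistic
  expect_equal(h0, h1, tolerance = 1e-12)
})

test_that("Dunn's post hoc flags only the shifted group and respects symmetry", {
  withr::with_seed(23, {
    gs <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 10))
  })
  d <- dunn_posthoc(gs)
  expect_equal(nrow(d), 3)
  ab <- d[d$comparison == "a vs b", ]
  expect_false(ab$reject)
  expect_gt(ab$adjusted_p, 0.05)
  expect_lt(d$adjusted_p[d$comparison == "a vs c"], 0.01)
  expect_lt(d$adjusted_p[d$comparison == "b vs c"], 0.01)

  same <- suppressWarnings(dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                             c = c(1, 2, 3))))
  expect_true(all(same$adjusted_p == 1))

  # equal rank separation gives equal adjusted p
  sym <- dunn_posthoc(list(lo = c(1, 2), mid = c(3, 4), hi = c(5, 6)))
  lo_mid <- sym$adjusted_p[sym$comparison == "lo vs mid"]
  mid_hi <- sym$adjusted_p[sym$comparison == "mid vs hi"]
  expect_equal(lo_mid, mid_hi, tolerance = 1e-12)

  # vs-control mode only compares against the named control
  vc <- dunn_posthoc(gs, comparisons = "vs_control", control = "a")
  expect_equal(nrow(vc), 2)
  expect_true(all(grepl("^a vs", vc$comparison)))
})

test_that("Holm-Sidak step-down follows its closed form and stays monotone", {
  one <- holm_sidak(0.02)
  expect_equal(one$p_adjusted, 0.02)

  hs <- holm_sidak(c(0.01, 0.04, 0.03))
  expect_equal(hs$p_adjusted[1], 1 - 0.99^3, tolerance = 1e-12)
  expect_equal(hs$p_adjusted[2], max(1 - 0.99^3, 1 - 0.97^2, 1 - 0.96),
               tolerance = 1e-12)
  expect_true(hs$reject[1])
  expect_false(any(hs$reject[2:3]))

  all_one <- holm_sidak(rep(1, 4))
  expect_true(all(all_one$p_adjusted == 1))
  expect_false(any(all_one$reject))

  withr::with_seed(41, p <- runif(20))
  out <- holm_sidak(p)
  expect_true(all(out$p_adjusted >= p))
  expect_true(all(out$p_adjusted <= 1))
  ord <- order(p)
  expect_true(all(diff(out$p_adjusted[ord]) >= -1e-15))
})

test_that("quadrant comparisons run one Welch t per quadrant with Holm-Sidak", {
  ms <- tibble::tibble(group = rep(c("A", "B"), each = 3),
                       mouse = paste0("m", 1:6),
                       pct_Q1 = c(80, 78, 82, 20, 22, 18),
                       pct_Q2 = c(10, 12, 8, 10, 8, 12),
                       pct_Q3 = c(5, 5, 5, 50, 52, 48),
                       pct_Q4 = c(5, 5, 5, 20, 18, 22))
  qt <- quadrant_tests(ms, "A", "B")
  expect_equal(nrow(qt), 4)
  expect_true(qt$reject[qt$quadrant == "Q1"])
  expect_true(qt$reject[qt$quadrant == "Q3"])
  expect_false(qt$reject[qt$quadrant == "Q2"])
  expect_error(quadrant_tests(ms, "A", "nope"), class = "ivtrack_validation_error")
})

test_that("test results serialize to a tidy comparison table", {
  tt <- list("x vs y" = mann_whitney(1:5, 6:10))
  tab <- tidy_tests(tt)
  expect_equal(tab$comparison, "x vs y")
  expect_equal(tab$n1, 5)
  expect_true(is.numeric(tab$raw_p))
})
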