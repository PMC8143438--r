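new_track_test <- function(statistic, p_value, method, n, adjusted = FALSE,
                           exact = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, adjusted = adjusted, exact = exact),
            class = "track_test")
}

#' @export
print.track_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.6g, p = %.6g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = ", "),
              if (x$adjusted) " [adjusted]" else ""))
  invisible(x)
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided rank-sum comparison of two independent samples. The U
#' statistic uses midranks for ties. The p-value is exact (full enumeration
#' of rank assignments) when requested, or in `"auto"` mode when the
#' smaller sample has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used. Exact mode falls back to the
#' approximation with a warning when ties make enumeration invalid.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return A `track_test`: `statistic` (U for `x`), `p_value`, `method`,
#'   `n`, `exact` flag.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.", class = "ivtrack_validation_error")
  }
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    warn("All values identical across both groups; no separation, p = 1.")
    return(new_track_test(u, 1, "Mann-Whitney U (degenerate: all values tied)",
                          c(n1, n2)))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      auto = min(n1, n2) <= 8 && !ties)
  if (use_exact && ties) {
    warn("Ties present: exact enumeration invalid, using the normal approximation.")
    use_exact <- FALSE
  }
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                             correct = TRUE))
  method <- if (use_exact) {
    "Mann-Whitney U (exact, two-sided)"
  } else {
    "Mann-Whitney U (normal approximation, tie-corrected, continuity-corrected)"
  }
  new_track_test(unname(res$statistic), res$p.value, method, c(n1, n2),
                 exact = use_exact)
}

#' Kruskal-Wallis rank test for three or more groups
#'
#' Tie-corrected H statistic, referred to a chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param groups List of at least three non-empty numeric samples.
#' @return A `track_test` with `statistic` = H and a `df` element.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_groups = 3)
  if (length(unique(unlist(groups))) == 1) {
    warn("All values identical across groups; H = 0, p = 1.")
    out <- new_track_test(0, 1, "Kruskal-Wallis (degenerate: all values tied)",
                          lengths(groups))
    out$df <- length(groups) - 1
    return(out)
  }
  res <- stats::kruskal.test(groups)
  out <- new_track_test(unname(res$statistic), res$p.value,
                        "Kruskal-Wallis rank sum test (tie-corrected)",
                        lengths(groups))
  out$df <- unname(res$parameter)
  out
}

check_groups <- function(groups, min_groups = 2) {
  if (!is.list(groups) || length(groups) < min_groups) {
    abort(sprintf("Need a list of at least %d groups.", min_groups),
          class = "ivtrack_validation_error")
  }
  if (any(lengths(groups) == 0)) {
    abort("Every group must be non-empty.", class = "ivtrack_validation_error")
  }
  invisible(groups)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from pooled-rank means with tie-corrected
#' variance:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum(t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' Raw two-sided p-values are adjusted for the number of comparisons made,
#' by Holm-Sidak step-down by default (Bonferroni available).
#'
#' @param groups Named (or unnamed) list of >= 3 non-empty numeric samples.
#' @param comparisons `"all_pairs"` (default) or `"vs_control"`.
#' @param control Name or index of the control group for `"vs_control"`
#'   (default: the first group).
#' @param adjust `"holm_sidak"` (default), `"bonferroni"` or `"none"`.
#' @param alpha Significance level for the reject flags.
#' @return Tidy tibble: `comparison`, `statistic` (z), `raw_p`,
#'   `adjusted_p`, `reject`, `method`, `n1`, `n2`.
#' @export
dunn_posthoc <- function(groups, comparisons = c("all_pairs", "vs_control"),
                         control = NULL, adjust = c("holm_sidak", "bonferroni", "none"),
                         alpha = 0.05) {
  comparisons <- match.arg(comparisons)
  adjust <- match.arg(adjust)
  check_groups(groups, min_groups = 3)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  n_all <- length(pooled)
  ranks <- rank(pooled)
  grp <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(ranks, grp, mean)
  n_i <- lengths(groups)
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts)
  sigma2_base <- n_all * (n_all + 1) / 12 -
    if (n_all > 1) tie_term / (12 * (n_all - 1)) else 0

  pairs <- if (comparisons == "all_pairs") {
    utils::combn(k, 2, simplify = FALSE)
  } else {
    ci <- if (is.null(control)) 1L else
      if (is.character(control)) match(control, names(groups)) else as.integer(control)
    if (is.na(ci) || ci < 1 || ci > k) {
      abort("Unknown control group.", class = "ivtrack_config_error")
    }
    lapply(setdiff(seq_len(k), ci), function(j) c(ci, j))
  }

  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- sigma2_base * (1 / n_i[i] + 1 / n_i[j])
    if (se2 <= 0) {
      warn("Zero rank variance (all values tied); z = 0, p = 1.")
      z <- 0
    } else {
      z <- (rbar[i] - rbar[j]) / sqrt(se2)
    }
    tibble::tibble(comparison = paste(names(groups)[i], "vs", names(groups)[j]),
                   statistic = unname(z),
                   raw_p = 2 * pnorm(-abs(z)),
                   n1 = n_i[i], n2 = n_i[j])
  })
  out <- dplyr::bind_rows(rows)
  adj <- switch(adjust,
                holm_sidak = holm_sidak(out$raw_p, alpha = alpha),
                bonferroni = tibble::tibble(p_adjusted = pmin(1, out$raw_p * nrow(out)),
                                            reject = pmin(1, out$raw_p * nrow(out)) <= alpha),
                none = tibble::tibble(p_adjusted = out$raw_p,
                                      reject = out$raw_p <= alpha))
  out$adjusted_p <- adj$p_adjusted
  out$reject <- adj$reject
  out$method <- sprintf("Dunn's test (tie-corrected), %s adjustment",
                        gsub("_", "-", adjust))
  out[, c("comparison", "statistic", "raw_p", "adjusted_p", "reject",
          "method", "n1", "n2")]
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-comparison correction: with the `m` raw p-values
#' sorted ascending, the i-th adjusted value is
#' `max over j <= i of (1 - (1 - p_(j))^(m - j + 1))`, clipped to 1 — so
#' adjusted values are monotone non-decreasing in the sorted order.
#' Hypotheses are rejected in sorted order while the adjusted p stays at or
#' below `alpha`; the first failure stops all further rejections.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Significance level (default 0.05).
#' @return Tibble in the input order: `p_raw`, `p_adjusted`, `reject`.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))  # smallest adjusted: 1 - 0.99^3
holm_sidak <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1].", class = "ivtrack_validation_error")
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  ok <- adj_sorted <= alpha
  reject_sorted <- cumprod(ok) == 1  # step-down: stop at first failure
  adj <- numeric(m); rej <- logical(m)
  adj[ord] <- adj_sorted
  rej[ord] <- reject_sorted
  tibble::tibble(p_raw = p, p_adjusted = adj, reject = rej)
}

#' Per-quadrant multiple-comparison t tests between two groups
#'
#' Compares the mouse-level quadrant percentages of two treatment groups,
#' one Welch t test per quadrant, with Holm-Sidak correction across the
#' four quadrants — the standard analysis of quadrant bar summaries.
#'
#' @param mouse_summary Mouse-level behaviour summary from
#'   [summarize_behaviour()] (`level = "mouse"`).
#' @param group_a,group_b The two group labels to compare.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `quadrant`, `statistic` (t), `df`, `raw_p`,
#'   `adjusted_p`, `reject`, `n1`, `n2`.
#' @export
quadrant_tests <- function(mouse_summary, group_a, group_b, alpha = 0.05) {
  for (g in c(group_a, group_b)) {
    if (!g %in% mouse_summary$group) {
      abort(sprintf("Group '%s' not present in the summary.", g),
            class = "ivtrack_validation_error")
    }
  }
  rows <- lapply(paste0("pct_Q", 1:4), function(col) {
    a <- mouse_summary[[col]][mouse_summary$group == group_a]
    b <- mouse_summary[[col]][mouse_summary$group == group_b]
    if (length(a) < 2 || length(b) < 2) {
      abort("Welch t needs at least 2 mice per group.",
            class = "ivtrack_validation_error")
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
    }
    tibble::tibble(quadrant = sub("pct_", "", col),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   raw_p = tt$p.value,
                   n1 = length(a), n2 = length(b))
  })
  out <- dplyr::bind_rows(rows)
  adj <- holm_sidak(out$raw_p, alpha = alpha)
  out$adjusted_p <- adj$p_adjusted
  out$reject <- adj$reject
  out[, c("quadrant", "statistic", "df", "raw_p", "adjusted_p", "reject",
          "n1", "n2")]
}

#' Serialize test results to a tidy table
#'
#' @param tests A `track_test` or list of them.
#' @return Tibble: `comparison`, `statistic`, `raw_p`, `method`, `n1`, `n2`.
#' @export
tidy_tests <- function(tests) {
  if (inherits(tests, "track_test")) tests <- list(tests)
  rows <- lapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    nm <- names(tests)[i]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- sprintf("test_%d", i)
    tibble::tibble(comparison = nm,
                   statistic = t$statistic, raw_p = t$p_value,
                   method = t$method,
                   n1 = t$n[1], n2 = if (length(t$n) > 1) t$n[2] else NA_integer_)
  })
  dplyr::bind_rows(rows)
}
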