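# Independent oracles: deliberately naive, loop-based implementations used to
# cross-check the package's vectorized code paths. They never call package
# internals.

# Step-by-step brute-force track metrics.
oracle_metrics <- function(pts) {
  pts <- pts[order(pts$frame), ]
  n <- nrow(pts)
  path <- 0
  for (i in 2:n) {
    path <- path + sqrt((pts$x_um[i] - pts$x_um[i - 1])^2 +
                          (pts$y_um[i] - pts$y_um[i - 1])^2 +
                          (pts$z_um[i] - pts$z_um[i - 1])^2)
  }
  disp <- sqrt((pts$x_um[n] - pts$x_um[1])^2 + (pts$y_um[n] - pts$y_um[1])^2 +
                 (pts$z_um[n] - pts$z_um[1])^2)
  dur <- (pts$t_s[n] - pts$t_s[1]) / 60
  list(path_length = path, displacement = disp, duration = dur,
       mean_velocity = path / dur,
       confinement = if (path > 0) disp / path else 0)
}

# Random valid track in the canonical long schema.
random_track <- function(id, n = 10, seed = 1, dt = 60) {
  withr::with_seed(seed, {
    tibble::tibble(track_id = id, frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
                   x_um = cumsum(rnorm(n, sd = 2)) + 100,
                   y_um = cumsum(rnorm(n, sd = 2)) + 100,
                   z_um = cumsum(rnorm(n, sd = 1)) + 50)
  })
}

# Exact two-sided Mann-Whitney p by full enumeration of rank splits
# (tie-free data only), matching the standard two-sided convention
# min(1, 2 * min(P(U <= u), P(U >= u))).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  us <- colSums(splits) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# 3D rotation matrix about an arbitrary axis.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(a, a) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s_
}

apply_affine <- function(track, rot = diag(3), shift = c(0, 0, 0), scale = 1) {
  xyz <- as.matrix(track[, c("x_um", "y_um", "z_um")]) %*% t(rot) * scale
  track$x_um <- xyz[, 1] + shift[1]
  track$y_um <- xyz[, 2] + shift[2]
  track$z_um <- xyz[, 3] + shift[3]
  track
}
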