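# Independent oracles and small fixture builders used across test files.

# Naive double-loop time-averaged MSD (the brute-force oracle the fast
# estimator must reproduce).
msd_oracle <- function(x, y, dt, max_lag_s) {
  n <- length(x)
  kmax <- min(n - 1L, floor(max_lag_s / dt + 1e-9))
  msd <- numeric(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }
    msd[k] <- acc / (n - k)
  }
  msd
}

# Brute-force point-to-polygon-boundary distance by dense boundary sampling.
dist_oracle <- function(p, ring, n_samples = 1e4) {
  vx <- ring[, 1L]; vy <- ring[, 2L]
  nx <- c(vx[-1L], vx[1L]); ny <- c(vy[-1L], vy[1L])
  seg_len <- sqrt((nx - vx)^2 + (ny - vy)^2)
  per_edge <- pmax(2L, ceiling(n_samples * seg_len / sum(seg_len)))
  best <- Inf
  for (e in seq_along(vx)) {
    tt <- seq(0, 1, length.out = per_edge[e])
    sx <- vx[e] + tt * (nx[e] - vx[e])
    sy <- vy[e] + tt * (ny[e] - vy[e])
    best <- min(best, min(sqrt((p[1] - sx)^2 + (p[2] - sy)^2)))
  }
  best
}

# A random uniformly sampled test trajectory.
random_traj <- function(n, dt = 0.125, scale = 1, seed = NULL, id = "r1") {
  if (!is.null(seed)) set.seed(seed)
  trajectory(id, t_s = (seq_len(n) - 1) * dt,
             x_um = cumsum(rnorm(n, 0, scale)),
             y_um = cumsum(rnorm(n, 0, scale)))
}

# Several well-separated Brownian walkers on a grid, for rendering.
grid_walkers <- function(n_particles, n_frames, D = 0.05, dt = 0.125,
                         spacing_um = 15, seed = 1) {
  lapply(seq_len(n_particles), function(i) {
    tr <- simulate_trajectory(
      motion_params(D_um2_s = D, frame_interval_s = dt, n_frames = n_frames,
                    seed = seed * 1000L + i),
      particle_id = paste0("g", i))
    tr$x_um <- tr$x_um + ((i - 1) %% 5) * spacing_um
    tr$y_um <- tr$y_um + ((i - 1) %/% 5) * spacing_um
    tr
  })
}
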