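test_that("instantaneous speeds match closed forms", {
  # x = t (1 um/s), lag 0.1 s
  tr <- trajectory("v", seq(0, 5, 0.1), seq(0, 5, 0.1), rep(0, 51))
  expect_equal(instantaneous_velocity(tr, 0.1), rep(1, 50))
  st <- trajectory("s", seq(0, 5, 0.1), rep(1, 51), rep(2, 51))
  expect_equal(instantaneous_velocity(st, 0.1), rep(0, 50))
  expect_error(instantaneous_velocity(tr, 0.15), "integer multiple")
  # Brownian mean speed: Rayleigh mean sqrt(pi * D / lag)
  D <- 1e-3; lag <- 0.1
  tr2 <- simulate_trajectory(motion_params(D_um2_s = D,
                                           frame_interval_s = lag,
                                           n_frames = 2e4, seed = 61))
  v <- instantaneous_velocity(tr2, lag)
  expect_equal(mean(v), sqrt(pi * D / lag), tolerance = 0.05)
})

test_that("distance to nuclei is the unsigned border distance", {
  sq <- nucleus_map(list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  expect_equal(distance_to_nuclei(c(0, 0), sq), 0)         # on a vertex
  expect_equal(distance_to_nuclei(c(5, 5), sq), 5)         # interior apothem
  expect_equal(distance_to_nuclei(c(15, 5), sq), 5)        # outside
  expect_equal(distance_to_nuclei(c(5, 0), sq), 0)         # on an edge
  expect_error(distance_to_nuclei(c(0, 0), list()), "NucleusMap")
})

test_that("border distances agree with a dense-sampling oracle", {
  map <- generate_nucleus_map(2, 2, nucleus_radius_um = 2, spacing_um = 6,
                              jitter_um = 0.5, seed = 62)
  set.seed(63)
  pts <- cbind(runif(100, -2, 10), runif(100, -2, 10))
  fast <- distance_to_nuclei(pts, map)
  slow <- vapply(seq_len(100), function(i) {
    min(vapply(map$polygons, function(rg) dist_oracle(pts[i, ], rg),
               numeric(1)))
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-3)
})

test_that("Van Hove histogram is normalised and reflection-symmetric", {
  set.seed(64)
  d <- rnorm(5000, 0, 0.012)
  a <- compute_van_hove(displacements = d, n_boot = 50, seed = 1)
  expect_equal(sum(a$probability), 1, tolerance = 1e-9)
  b <- compute_van_hove(displacements = -d, n_boot = 50, seed = 1)
  # the mirrored histogram is bit-identical; the fitted quantities agree to
  # optimiser precision
  expect_identical(rev(b$probability), a$probability)
  expect_equal(b$gaussian_fit$sigma_um, a$gaussian_fit$sigma_um,
               tolerance = 1e-6)
  expect_equal(b$tail_excess, a$tail_excess, tolerance = 1e-6)
  expect_equal(b$excess_kurtosis, a$excess_kurtosis, tolerance = 1e-9)
})

test_that("thermal motion gives sigma^2 = 2 D tau and no active flag", {
  D <- 1e-3; lag <- 0.1
  trajs <- lapply(1:5, function(i) {
    simulate_trajectory(motion_params(D_um2_s = D, frame_interval_s = lag,
                                      n_frames = 10001, seed = 650 + i),
                        paste0("t", i))
  })
  vh <- compute_van_hove(trajs, lag_s = lag, seed = 1)
  expect_gte(vh$n_displacements, 1e5)
  expect_equal(vh$gaussian_fit$sigma_um^2, 2 * D * lag, tolerance = 0.05)
  expect_lt(abs(vh$excess_kurtosis), 0.05)
  expect_false(vh$active_processes_detected)
  expect_equal(vh$tail_excess, 0, tolerance = 1e-6)
})

test_that("heavy-tailed burst admixtures raise the active flag", {
  trajs <- lapply(1:4, function(i) {
    simulate_trajectory(motion_params(
      D_um2_s = 1e-3, frame_interval_s = 0.1, n_frames = 2501,
      active_burst = list(rate = 0.05, scale_um = 0.05), seed = 660 + i),
      paste0("a", i))
  })
  vh <- compute_van_hove(trajs, lag_s = 0.1, seed = 1)
  expect_true(vh$active_processes_detected)
  expect_gt(vh$tail_excess, 3 * vh$tail_excess_se)
  expect_gt(vh$excess_kurtosis, 1)
})

test_that("a too-narrow Gaussian window is rejected", {
  set.seed(66)
  expect_error(compute_van_hove(displacements = rnorm(1000, 0, 0.01),
                                bin_width_um = 0.05,
                                gaussian_window_um = c(-0.03, 0.03)),
               "fewer than 3")
})

test_that("proximity partitioning separates confined from free walkers", {
  map <- generate_nucleus_map(3, 3, nucleus_radius_um = 2, spacing_um = 7,
                              seed = 67)
  mk <- function(D, offset, i, id) {
    tr <- simulate_trajectory(motion_params(D_um2_s = D,
                                            frame_interval_s = 0.1,
                                            n_frames = 2501, seed = i),
                              id)
    tr$x_um <- tr$x_um + offset[1]; tr$y_um <- tr$y_um + offset[2]
    tr
  }
  # near-nucleus walkers (adjacent to a border) diffuse at half the far D
  near <- lapply(1:2, function(i)
    mk(5e-4, map$centers[i, ] + c(2.3, 0), 670 + i, paste0("n", i)))
  far <- lapply(1:2, function(i)
    mk(1e-3, c(30 + 5 * i, 30), 680 + i, paste0("f", i)))
  part <- partition_by_proximity(c(near, far), map, threshold_um = 1.5,
                                 lag_s = 0.1, n_boot = 50, seed = 1)
  expect_false(part$comparison$underpowered)
  expect_equal(part$comparison$variance_ratio, 0.5, tolerance = 0.2)
  expect_lt(part$comparison$near_sigma_um, part$comparison$far_sigma_um)
  expect_lt(part$comparison$wilcox_p, 0.05)
})

test_that("identical dynamics in both groups is usually non-significant", {
  map <- nucleus_map(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  rejected <- 0L
  for (rep in 1:20) {
    trajs <- lapply(1:2, function(i) {
      tr <- simulate_trajectory(motion_params(D_um2_s = 1e-3,
                                              frame_interval_s = 0.1,
                                              n_frames = 301,
                                              seed = 700 + 10 * rep + i),
                                paste0("x", i))
      tr$x_um <- tr$x_um + i * 4  # one starts nearer the nucleus
      tr
    })
    part <- partition_by_proximity(trajs, map, threshold_um = 5,
                                   lag_s = 0.1, n_boot = 10, seed = 1)
    if (isTRUE(part$comparison$wilcox_p < 0.05)) rejected <- rejected + 1L
  }
  expect_lte(rejected, 3L)  # >= 90% of replicates non-significant
})

test_that("an empty proximity group is flagged as underpowered", {
  map <- nucleus_map(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  tr <- simulate_trajectory(motion_params(D_um2_s = 1e-3,
                                          frame_interval_s = 0.1,
                                          n_frames = 200, seed = 68), "far1")
  tr$x_um <- tr$x_um + 100
  part <- partition_by_proximity(list(tr), map, threshold_um = 2)
  expect_equal(part$near$n, 0L)
  expect_true(part$comparison$underpowered)
})
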