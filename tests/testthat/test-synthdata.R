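test_that("sheet geometry follows the monolayer and Cu areal-density rules", {
  # forced 100 nm disc, 2 nm height: 2 layers, Cu = round(3.8 * pi * 50^2 * 2)
  p <- generate_sheet_population(1, c(100, 100), height_slope = 0.02,
                                 noise_cv = 0, height_scatter_cv = 0, seed = 1)
  expect_equal(p$height_nm, 2)
  expect_equal(p$n_layers, 2L)
  expect_equal(p$n_cu, 59690)
  # invariants on a noisy population
  pop <- generate_sheet_population(200, seed = 11)
  expect_equal(pop$n_layers, round(pop$height_nm / 1.0))
  expect_equal(pop$n_cu,
               round(3.8 * pi * (pop$diameter_nm / 2)^2 * pop$n_layers))
  expect_gt(cor(pop$diameter_nm, pop$height_nm), 0)
})

test_that("noise-free brightness is an exact power law of diameter", {
  pop <- generate_sheet_population(50, brightness_exponent = 0.5,
                                   noise_cv = 0, seed = 2)
  fit <- lm(log(pop$true_brightness) ~ log(pop$diameter_nm))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-10)
  expect_lt(max(abs(resid(fit))), 1e-10)
})

test_that("default cohort reproduces the observed size band", {
  pop <- generate_sheet_population(78, seed = 7)
  expect_true(all(pop$diameter_nm >= 20 & pop$diameter_nm <= 300))
  # heights span roughly the 1-13 nm band (lognormal scatter widens it a bit)
  expect_true(all(pop$height_nm >= 1 & pop$height_nm <= 16))
  expect_gt(sum(pop$height_nm <= 13) / nrow(pop), 0.95)
})

test_that("degenerate population arguments are rejected", {
  expect_error(generate_sheet_population(0), "positive integer")
  expect_error(generate_sheet_population(5, c(300, 20)), "interval")
  expect_error(generate_sheet_population(5, c(0, 100)), "interval")
  expect_error(generate_sheet_population(5, brightness_exponent = -1))
})

test_that("Brownian steps have the closed-form variance 2*D*dt", {
  D <- 0.25; dt <- 0.1; n <- 1e5
  tr <- simulate_trajectory(motion_params(D_um2_s = D, frame_interval_s = dt,
                                          n_frames = n, seed = 3))
  s <- sd(diff(tr$x_um))
  expect_equal(s, sqrt(2 * D * dt), tolerance = 0.01)
  expect_equal(sd(diff(tr$y_um)), sqrt(2 * D * dt), tolerance = 0.01)
})

test_that("infinite viscosity freezes the particle", {
  tr <- simulate_trajectory(motion_params(viscosity_Pa_s = Inf,
                                          n_frames = 100, seed = 4))
  expect_true(all(tr$x_um == tr$x_um[1]))
  expect_true(all(tr$y_um == tr$y_um[1]))
})

test_that("pooled MSD slope recovers the Stokes-Einstein forward value", {
  # R = 50 nm, eta = 1.0 Pa s, T = 295 K: D = kB*T / (6 pi eta R)
  D_true <- 1.380649e-23 * 295 / (6 * pi * 1.0 * 50e-9) * 1e12
  mp <- function(i) motion_params(stokes_radius_nm = 50, temperature_K = 295,
                                  viscosity_Pa_s = 1.0,
                                  frame_interval_s = 0.125, n_frames = 1000,
                                  seed = 5000 + i)
  n_traj <- 500
  msum <- NULL
  for (i in seq_len(n_traj)) {
    m <- compute_msd(simulate_trajectory(mp(i)), max_lag_s = 25)
    msum <- if (is.null(msum)) m$msd_um2 else msum + m$msd_um2
  }
  pooled <- data.frame(lag_s = (1:200) * 0.125, msd_um2 = msum / n_traj,
                       n_pairs = 1000 - 1:200)
  class(pooled) <- c("MSDCurve", "data.frame")
  D_hat <- fit_diffusion(pooled, 25)$D_um2_s
  expect_equal(D_hat, D_true, tolerance = 0.05)
})

test_that("rendered spots integrate to the analytic Gaussian flux", {
  tr <- trajectory("s", 0, 20, 30)
  mv <- render_movie(tr, pixel_size_um = 1, psf_sigma_px = 2,
                     amplitudes = 100, background = 0)
  expect_equal(sum(mv$frames), 2 * pi * 100 * 2^2, tolerance = 0.01)
  # noise-free intensity budget: background + spot integrals within 0.1%
  mv2 <- render_movie(tr, 1, 2, amplitudes = 100, background = 10)
  expect_equal(sum(mv2$frames),
               10 * prod(dim(mv2$frames)[1:2]) + 2 * pi * 100 * 4,
               tolerance = 1e-3)
})

test_that("a spotless movie is flat background", {
  tr <- trajectory("s", 0, 5, 5)
  mv <- render_movie(tr, 1, 2, amplitudes = 0, background = 10)
  expect_true(all(mv$frames == 10))
})

test_that("out-of-frame positions are flagged, not dropped", {
  tr <- trajectory("s", c(0, 1), c(5, 50), c(5, 5))
  mv <- render_movie(tr, 1, 2, amplitudes = 100, dim_px = c(20, 20),
                     origin_um = c(0, 0))
  expect_equal(nrow(mv$clipped), 1L)
  expect_equal(mv$clipped$frame, 2L)
})

test_that("seeded generators are bit-reproducible", {
  a <- render_movie(trajectory("s", 0, 5, 5), 1, 2, amplitudes = 50,
                    background = 5, noise_model = "poisson", seed = 9)
  b <- render_movie(trajectory("s", 0, 5, 5), 1, 2, amplitudes = 50,
                    background = 5, noise_model = "poisson", seed = 9)
  expect_identical(a$frames, b$frames)
  p1 <- generate_sheet_population(40, seed = 6)
  p2 <- generate_sheet_population(40, seed = 6)
  expect_identical(p1$diameter_nm, p2$diameter_nm)
  t1 <- simulate_trajectory(motion_params(n_frames = 50, seed = 8))
  t2 <- simulate_trajectory(motion_params(n_frames = 50, seed = 8))
  expect_identical(t1$x_um, t2$x_um)
  s1 <- simulate_saturation_sweep(1e5, 100, c(1, 10, 100), seed = 10)
  s2 <- simulate_saturation_sweep(1e5, 100, c(1, 10, 100), seed = 10)
  expect_identical(s1$detected_counts_per_s, s2$detected_counts_per_s)
  m1 <- generate_nucleus_map(5, 5, 2, 6, jitter_um = 0.4, seed = 12)
  m2 <- generate_nucleus_map(5, 5, 2, 6, jitter_um = 0.4, seed = 12)
  expect_identical(m1$polygons, m2$polygons)
})

test_that("saturation sweep obeys the half-saturation and zero-power limits", {
  sw <- simulate_saturation_sweep(1e6, 150, c(0, 150), integration_s = 1,
                                  noise = "none", directions = "up")
  expect_equal(sw$detected_counts_per_s[sw$P_exc_uW == 0], 0)
  expect_equal(sw$detected_counts_per_s[sw$P_exc_uW == 150], 1e6 / 2)
})

test_that("nucleus maps are non-overlapping jittered hexagonal arrays", {
  m1 <- generate_nucleus_map(1, 1, nucleus_radius_um = 2, jitter_um = 0,
                             spacing_um = 5)
  expect_length(m1$polygons, 1L)
  expect_equal(nrow(m1$polygons[[1]]), 24L)
  expect_equal(colMeans(m1$polygons[[1]]), c(x_um = 0, y_um = 0),
               tolerance = 1e-12)
  expect_equal(sqrt(rowSums(m1$polygons[[1]]^2)), rep(2, 24))
  m <- generate_nucleus_map(4, 4, nucleus_radius_um = 2, spacing_um = 5,
                            jitter_um = 0.4, seed = 13)
  cd <- as.matrix(dist(m$centers))
  diag(cd) <- Inf
  expect_gt(min(cd), 2 * 2)  # boundaries strictly separated
  expect_error(generate_nucleus_map(2, 2, nucleus_radius_um = 3,
                                    spacing_um = 5), "twice")
})
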