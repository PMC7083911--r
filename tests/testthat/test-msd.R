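test_that("fast MSD matches the brute-force double loop exactly", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    tr <- random_traj(n, dt = 0.125, seed = NULL)
    m <- compute_msd(tr, max_lag_s = 25)
    expect_equal(m$msd_um2, msd_oracle(tr$x_um, tr$y_um, 0.125, 25),
                 tolerance = 1e-10)
    expect_equal(m$n_pairs, n - seq_along(m$msd_um2))
  }
})

test_that("MSD limits: stationary and ballistic motion", {
  st <- trajectory("s", 0:9, rep(1, 10), rep(2, 10))
  expect_true(all(compute_msd(st, 5)$msd_um2 == 0))
  ba <- trajectory("b", 0:9, 0:9, rep(0, 10))  # x = v t, v = 1 um/s
  m <- compute_msd(ba, 5)
  expect_equal(m$msd_um2[m$lag_s == 2], 4)     # (v tau)^2
  expect_equal(m$msd_um2, m$lag_s^2)
})

test_that("the single-step estimator averages consecutive displacements", {
  tr <- random_traj(50, dt = 0.1, seed = 32)
  m <- compute_msd(tr, estimator = "single_step")
  expect_equal(nrow(m), 1L)
  expect_equal(m$lag_s, 0.1)
  expect_equal(m$msd_um2, mean(diff(tr$x_um)^2 + diff(tr$y_um)^2))
})

test_that("non-uniform sampling is rejected", {
  tr <- trajectory("g", c(0, 1, 2, 5), 1:4, 1:4)
  expect_error(compute_msd(tr), "uniform")
})

test_that("diffusion fitting inverts exact MSD lines", {
  lag <- (1:20) * 0.5
  exact <- structure(data.frame(lag_s = lag, msd_um2 = 4 * 1.0 * lag,
                                n_pairs = 100 - 1:20),
                     class = c("MSDCurve", "data.frame"))
  fit <- fit_diffusion(exact, 25)
  expect_equal(fit$D_um2_s, 1.0, tolerance = 1e-12)
  expect_equal(fit$intercept_um2, 0)
  # single lag: D = msd / (4 tau)
  one <- structure(data.frame(lag_s = 1, msd_um2 = 4, n_pairs = 10),
                   class = c("MSDCurve", "data.frame"))
  expect_equal(fit_diffusion(one, 25)$D_um2_s, 1.0)
  # intercept absorbs a localisation-noise offset
  off <- structure(data.frame(lag_s = lag, msd_um2 = 4 * 0.5 * lag + 0.02,
                              n_pairs = 100 - 1:20),
                   class = c("MSDCurve", "data.frame"))
  fo <- fit_diffusion(off, 25, with_intercept = TRUE)
  expect_equal(fo$D_um2_s, 0.5, tolerance = 1e-10)
  expect_equal(fo$intercept_um2, 0.02, tolerance = 1e-10)
  # the fit window is honoured
  expect_equal(fit_diffusion(exact, 5)$n_lags, sum(lag <= 5))
  # degenerate all-zero MSD
  zero <- structure(data.frame(lag_s = lag, msd_um2 = 0, n_pairs = 10),
                    class = c("MSDCurve", "data.frame"))
  fz <- fit_diffusion(zero, 25)
  expect_equal(fz$D_um2_s, 0)
  expect_true(fz$degenerate)
})

test_that("median fitted D recovers the truth on slow in-vivo-like tracks", {
  D <- 1e-3
  Ds <- vapply(1:200, function(i) {
    tr <- simulate_trajectory(motion_params(D_um2_s = D,
                                            frame_interval_s = 0.125,
                                            n_frames = 1000,
                                            seed = 7000 + i))
    fit_diffusion(compute_msd(tr, 25), 25)$D_um2_s
  }, numeric(1))
  expect_equal(median(Ds), D, tolerance = 0.10)
})

test_that("glycerol-water viscosity matches published table values", {
  # pure water at 20 C: 1.002 mPa s
  expect_equal(glycerol_viscosity(293.15, 0), 1.002e-3, tolerance = 0.05)
  # pure glycerol at 20 C: ~1.41 Pa s
  expect_equal(glycerol_viscosity(293.15, 1), 1.412, tolerance = 0.05)
  # 50 w% at 25 C: ~5.0 mPa s (tabulated 6.05 at 20 C, 5.02 at 25 C)
  expect_equal(glycerol_viscosity(298.15, 0.5), 5.0e-3, tolerance = 0.10)
  # strictly decreasing in temperature
  expect_gt(glycerol_viscosity(290, 1), glycerol_viscosity(300, 1))
  ts <- seq(280, 360, 5)
  expect_true(all(diff(glycerol_viscosity(ts, 0.8)) < 0))
  expect_error(glycerol_viscosity(250, 1), "K")
  expect_error(glycerol_viscosity(300, 1.2), "fraction")
})

test_that("Stokes-Einstein sizing and the anisotropy correction", {
  h <- stokes_radius(4.3214e-3, T_K = 295, eta_Pa_s = 1.0, A_correction = 1)
  expect_equal(h$R_stokes_nm, 50, tolerance = 1e-3)
  h2 <- stokes_radius(4.3214e-3, 295, 1.0, A_correction = 1.49)
  expect_equal(h2$R_hydro_nm, 1.49 * h2$R_stokes_nm)
  expect_equal(h2$R_hydro_nm, 74.5, tolerance = 1e-3)
  expect_gte(h2$R_hydro_nm, h2$R_stokes_nm)
  # R scales as 1/(eta D)
  expect_equal(stokes_radius(4.3214e-3, 295, 2.0, 1)$R_stokes_nm,
               h$R_stokes_nm / 2)
  expect_equal(stokes_radius(2 * 4.3214e-3, 295, 1.0, 1)$R_stokes_nm,
               h$R_stokes_nm / 2)
  expect_error(stokes_radius(0), "positive")
})

test_that("SI and micrometre unit paths agree exactly", {
  a <- stokes_radius(4.3214e-3, 295, 1.0, 1.49, D_units = "um2_s")
  b <- stokes_radius(4.3214e-3 * 1e-12, 295, 1.0, 1.49, D_units = "m2_s")
  expect_equal(a$R_hydro_nm, b$R_hydro_nm, tolerance = 1e-12)
})

test_that("Perrin oblate friction is 1 for a sphere and grows with flatness", {
  expect_equal(perrin_oblate_friction(1), 1)
  f <- perrin_oblate_friction(c(0.5, 0.1, 0.02))
  expect_true(all(diff(f) > 0))
  expect_gt(f[1], 1)
  expect_error(perrin_oblate_friction(0), "aspect")
})

test_that("size-brightness correlation recovers imposed power laws", {
  # build a cohort whose sizes come from Brownian tracks and impose
  # mass = c * d_hat^0.5 using the *recovered* diameters (noise-free limit)
  set.seed(41)
  d_true <- exp(runif(40, log(50), log(300)))
  trajs <- lapply(seq_along(d_true), function(i) {
    simulate_trajectory(motion_params(stokes_radius_nm = d_true[i] / 2 / 1.49,
                                      viscosity_Pa_s = 1.0,
                                      frame_interval_s = 0.125,
                                      n_frames = 1000, seed = 8000 + i),
                        particle_id = sprintf("q%02d", i))
  })
  d_hat <- vapply(trajs, function(tr) {
    2 * stokes_radius(fit_diffusion(compute_msd(tr, 25), 25)$D_um2_s,
                      295, 1.0, 1.49)$R_hydro_nm
  }, numeric(1))
  for (i in seq_along(trajs)) trajs[[i]]$mass <- 3 * d_hat[i]^0.5
  res <- size_brightness_correlation(trajs, seed = 1, n_boot = 200)
  expect_equal(res$fit$exponent, 0.5, tolerance = 0.04)  # 0.5 +/- 0.02
  # recovered sizes correlate with the imposed truth
  expect_gt(cor(res$table$d_hydro_nm, d_true, method = "spearman"), 0)
})

test_that("a unit exponent survives 20% brightness scatter", {
  set.seed(42)
  n <- 300
  # recordings long relative to the 25 s fit window, so size-estimation
  # noise (errors-in-variables attenuation of the log-log slope) stays
  # small against the imposed 20% brightness scatter
  d_true <- exp(runif(n, log(20), log(300)))
  trajs <- lapply(seq_len(n), function(i) {
    tr <- simulate_trajectory(motion_params(
      stokes_radius_nm = d_true[i] / 2 / 1.49, viscosity_Pa_s = 1.0,
      frame_interval_s = 0.125, n_frames = 3000, seed = 9000 + i),
      particle_id = sprintf("u%03d", i))
    sdl <- sqrt(log(1 + 0.2^2))
    tr$mass <- 2 * d_true[i]^1.0 * rlnorm(1, -sdl^2 / 2, sdl)
    tr
  })
  res <- size_brightness_correlation(trajs, seed = 2, n_boot = 200)
  expect_equal(res$fit$exponent, 1.0, tolerance = 0.1)
  # larger sheets are brighter: positive rank correlation, p < 0.01
  ct <- cor.test(res$table$R_hydro_nm, res$table$max_mass,
                 method = "spearman", alternative = "greater", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("short degenerate tracks are excluded with a reason", {
  good <- lapply(1:3, function(i) {
    tr <- simulate_trajectory(motion_params(D_um2_s = 0.01,
                                            frame_interval_s = 0.1,
                                            n_frames = 500, seed = 50 + i),
                              paste0("ok", i))
    tr$mass <- 10
    tr
  })
  frozen <- simulate_trajectory(motion_params(viscosity_Pa_s = Inf,
                                              n_frames = 500, seed = 54),
                                "frozen")
  frozen$mass <- 5
  res <- size_brightness_correlation(c(good, list(frozen)), seed = 3,
                                     n_boot = 50)
  expect_equal(nrow(res$table), 3L)
  expect_equal(res$excluded$particle_id, "frozen")
  expect_error(size_brightness_correlation(good[1:2]), "at least 3")
})
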