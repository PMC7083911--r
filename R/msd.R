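#' Mean-square displacement of a trajectory
#'
#' The default `time_averaged` estimator is the standard overlapping
#' time-average: at integer lag k, the mean of
#' (x[i+k]-x[i])^2 + (y[i+k]-y[i])^2 over all i, for every lag up to
#' `max_lag_s`. The `single_step` estimator averages only consecutive
#' single-step square displacements and returns one value at the frame
#' interval; it is provided for fidelity with the classical step-wise
#' definition but cannot produce a lag-resolved curve.
#'
#' @param traj a [trajectory()]; must be uniformly sampled.
#' @param max_lag_s largest lag to evaluate, s (default 25).
#' @param estimator `"time_averaged"` or `"single_step"`.
#' @return An `"MSDCurve"` data frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_s = 25,
                        estimator = c("time_averaged", "single_step")) {
  estimator <- match.arg(estimator)
  if (!inherits(traj, "Trajectory")) stop("`traj` must be a Trajectory")
  if (nrow(traj) < 2L) stop("trajectory must have >= 2 points", call. = FALSE)
  dt <- .frame_interval(traj$t_s)
  x <- traj$x_um; y <- traj$y_um; n <- length(x)
  if (estimator == "single_step") {
    sq <- diff(x)^2 + diff(y)^2
    out <- data.frame(lag_s = dt, msd_um2 = mean(sq), n_pairs = n - 1L)
  } else {
    kmax <- min(n - 1L, floor(max_lag_s / dt + 1e-9))
    if (kmax < 1L) stop("`max_lag_s` shorter than one frame interval",
                        call. = FALSE)
    ks <- seq_len(kmax)
    msd <- vapply(ks, function(k) {
      dxk <- x[(k + 1L):n] - x[1L:(n - k)]
      dyk <- y[(k + 1L):n] - y[1L:(n - k)]
      mean(dxk^2 + dyk^2)
    }, numeric(1))
    out <- data.frame(lag_s = ks * dt, msd_um2 = msd, n_pairs = n - ks)
  }
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Weighted least squares of msd = 4*D*lag (optionally + intercept) over
#' lags up to `max_lag_s`, with weights equal to the number of displacement
#' pairs per lag. The through-origin fit is the default; the optional
#' intercept absorbs the static localisation-noise offset (4*sigma_loc^2).
#' A negative fitted D is clipped to zero and flagged.
#'
#' @param msd an `"MSDCurve"` from [compute_msd()].
#' @param max_lag_s fit window, s (default 25).
#' @param with_intercept include an intercept term?
#' @return A `"DiffusionFit"` list: `D_um2_s`, `intercept_um2`,
#'   `max_lag_s`, `r_squared`, `n_lags`, `clipped`, `degenerate`.
#' @export
fit_diffusion <- function(msd, max_lag_s = 25, with_intercept = FALSE) {
  if (!inherits(msd, "MSDCurve")) stop("`msd` must be an MSDCurve")
  use <- msd$lag_s <= max_lag_s + 1e-9
  d <- msd[use, , drop = FALSE]
  if (nrow(d) < (1L + with_intercept)) {
    stop("need at least ", 1L + with_intercept, " usable lag(s)", call. = FALSE)
  }
  degenerate <- all(d$msd_um2 == 0)
  if (degenerate) {
    return(structure(list(D_um2_s = 0, intercept_um2 = 0,
                          max_lag_s = max_lag_s, r_squared = NA_real_,
                          n_lags = nrow(d), clipped = FALSE,
                          degenerate = TRUE),
                     class = "DiffusionFit"))
  }
  fit <- if (with_intercept) {
    stats::lm(msd_um2 ~ I(4 * lag_s), data = d, weights = d$n_pairs)
  } else {
    stats::lm(msd_um2 ~ 0 + I(4 * lag_s), data = d, weights = d$n_pairs)
  }
  cf <- stats::coef(fit)
  D <- unname(cf[["I(4 * lag_s)"]])
  icpt <- if (with_intercept) unname(cf[["(Intercept)"]]) else 0
  clipped <- D < 0
  if (clipped) D <- 0
  pred <- stats::fitted(fit)
  ss_res <- sum(d$n_pairs * (d$msd_um2 - pred)^2)
  ss_tot <- sum(d$n_pairs * (d$msd_um2 -
                  stats::weighted.mean(d$msd_um2, d$n_pairs))^2)
  structure(list(D_um2_s = D, intercept_um2 = icpt, max_lag_s = max_lag_s,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_lags = nrow(d), clipped = clipped, degenerate = FALSE),
            class = "DiffusionFit")
}

#' Dynamic viscosity of glycerol-water mixtures
#'
#' Temperature-composition correlation for the dynamic viscosity of
#' glycerol-water mixtures (Cheng 2008, Ind. Eng. Chem. Res. 47:3285),
#' valid over roughly 0-100 degC and the full composition range. The
#' mixture viscosity interpolates between the pure-water and pure-glycerol
#' exponential laws with a composition- and temperature-dependent weight.
#'
#' @param T_K absolute temperature, K (273 < T < 373).
#' @param glycerol_mass_fraction mass fraction of glycerol in `[0, 1]`.
#' @return Dynamic viscosity in Pa s.
#' @export
glycerol_viscosity <- function(T_K, glycerol_mass_fraction = 1) {
  if (any(T_K <= 273) || any(T_K >= 373)) {
    stop("`T_K` must be within (273, 373) K", call. = FALSE)
  }
  cm <- glycerol_mass_fraction
  if (any(cm < 0) || any(cm > 1)) {
    stop("`glycerol_mass_fraction` must be in [0, 1]", call. = FALSE)
  }
  tc <- T_K - 273.15
  mu_w <- 1.790 * exp((-1230 - tc) * tc / (36100 + 360 * tc))   # cP
  mu_g <- 12100 * exp((-1233 + tc) * tc / (9900 + 70 * tc))     # cP
  a <- 0.705 - 0.0017 * tc
  b <- (4.9 + 0.036 * tc) * a^2.5
  alpha <- 1 - cm + a * b * cm * (1 - cm) / (a * cm + b * (1 - cm))
  mu <- mu_w^alpha * mu_g^(1 - alpha)                           # cP
  mu * 1e-3                                                     # Pa s
}

#' Stokes-Einstein radius with spheroid anisotropy correction
#'
#' Computes the sphere-equivalent Stokes radius R = kB*T / (6 pi eta D) and
#' multiplies it by the anisotropy correction factor `A_correction`
#' (default 1.49) that maps the sphere-equivalent radius of a thin
#' disc-like spheroid onto its hydrodynamic radius.
#'
#' @param D diffusion coefficient, in um^2/s by default.
#' @param T_K absolute temperature, K.
#' @param eta_Pa_s dynamic viscosity, Pa s.
#' @param A_correction dimensionless anisotropy factor (>= 1 for
#'   disc-like particles).
#' @param D_units `"um2_s"` or `"m2_s"`.
#' @return A `"HydroResult"` list: `R_stokes_nm`, `R_hydro_nm`,
#'   `A_correction`, `T_K`, `eta_Pa_s`, `D_um2_s`.
#' @export
stokes_radius <- function(D, T_K = 295, eta_Pa_s = 1.0, A_correction = 1.49,
                          D_units = c("um2_s", "m2_s")) {
  D_units <- match.arg(D_units)
  if (!is.numeric(D) || D <= 0) stop("`D` must be positive", call. = FALSE)
  .assert_scalar_pos(T_K, "T_K"); .assert_scalar_pos(eta_Pa_s, "eta_Pa_s")
  D_m2_s <- if (D_units == "um2_s") D * 1e-12 else D
  R_m <- .kB * T_K / (6 * pi * eta_Pa_s * D_m2_s)
  structure(list(R_stokes_nm = R_m * 1e9,
                 R_hydro_nm = A_correction * R_m * 1e9,
                 A_correction = A_correction, T_K = T_K,
                 eta_Pa_s = eta_Pa_s, D_um2_s = D_m2_s * 1e12),
            class = "HydroResult")
}

#' Perrin orientation-averaged friction factor for an oblate spheroid
#'
#' Auxiliary exploration tool: the ratio f/f0 of the orientation-averaged
#' translational friction of an oblate spheroid (equatorial semi-axis a,
#' polar semi-axis c < a) to that of the equal-volume sphere,
#' f/f0 = sqrt(1 - p^2) / (p^(2/3) * atan(sqrt(1 - p^2) / p)) with
#' p = c/a. It is NOT the source of the default anisotropy factor 1.49,
#' which is treated as a given constant for thin nanosheets.
#'
#' @param aspect_ratio p = c/a in (0, 1].
#' @return The dimensionless friction ratio f/f0 (>= 1).
#' @export
perrin_oblate_friction <- function(aspect_ratio) {
  p <- aspect_ratio
  if (any(p <= 0) || any(p > 1)) stop("`aspect_ratio` must be in (0, 1]",
                                      call. = FALSE)
  ifelse(p == 1, 1,
         sqrt(1 - p^2) / (p^(2 / 3) * atan(sqrt(1 - p^2) / p)))
}

#' Correlate hydrodynamic size with fluorescence brightness
#'
#' For each trajectory: fit the diffusion coefficient from its MSD
#' ([compute_msd()] + [fit_diffusion()]), convert to a corrected
#' hydrodynamic radius ([stokes_radius()]), and take the maximum integrated
#' brightness ([trajectory_max_mass()]). Then fit a power law
#' mass = prefactor * diameter^exponent by least squares in log-log space,
#' with a seeded bootstrap confidence interval on the exponent.
#' Trajectories whose fitted D is not positive are excluded with a logged
#' reason.
#'
#' @param trajs list of [trajectory()] objects (>= 3).
#' @param T_K,eta_Pa_s,A_correction physical conditions for the sizing.
#' @param fit_max_lag_s MSD fit window, s (default 25).
#' @param with_intercept pass an intercept to [fit_diffusion()] to absorb
#'   localisation noise.
#' @param n_boot bootstrap resamples for the exponent CI.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return A `"SizeBrightnessTable"` list: `table` (one row per retained
#'   trajectory: `particle_id`, `D_um2_s`, `R_stokes_nm`, `R_hydro_nm`,
#'   `d_hydro_nm`, `max_mass`, `n_points`), `fit` (`prefactor`, `exponent`,
#'   `exponent_ci`, `n_boot`), `excluded` (id + reason), `conditions`.
#' @export
size_brightness_correlation <- function(trajs, T_K = 295, eta_Pa_s = 1.0,
                                        A_correction = 1.49,
                                        fit_max_lag_s = 25,
                                        with_intercept = FALSE,
                                        n_boot = 1000, conf = 0.95,
                                        seed = NULL) {
  if (length(trajs) < 3L) stop("need at least 3 trajectories", call. = FALSE)
  rows <- list(); excluded <- list()
  for (tr in trajs) {
    id <- tr$particle_id[1L]
    fit <- fit_diffusion(compute_msd(tr, fit_max_lag_s), fit_max_lag_s,
                         with_intercept)
    if (fit$degenerate || fit$clipped || fit$D_um2_s <= 0) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(particle_id = id, reason = "non-positive fitted D")
      next
    }
    hy <- stokes_radius(fit$D_um2_s, T_K, eta_Pa_s, A_correction)
    rows[[length(rows) + 1L]] <- data.frame(
      particle_id = id, D_um2_s = fit$D_um2_s,
      R_stokes_nm = hy$R_stokes_nm, R_hydro_nm = hy$R_hydro_nm,
      d_hydro_nm = 2 * hy$R_hydro_nm,
      max_mass = trajectory_max_mass(tr), n_points = nrow(tr))
  }
  if (length(rows) < 3L) {
    stop("fewer than 3 trajectories with a valid size", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  logm <- log(tab$max_mass); logd <- log(tab$d_hydro_nm)
  cf <- stats::coef(stats::lm(logm ~ logd))
  boots <- local_seed(seed, replicate(n_boot, {
    i <- sample.int(nrow(tab), replace = TRUE)
    if (length(unique(logd[i])) < 2L) return(NA_real_)
    stats::coef(stats::lm(logm[i] ~ logd[i]))[[2L]]
  }))
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(
    table = tab,
    fit = list(prefactor = exp(unname(cf[[1L]])),
               exponent = unname(cf[[2L]]), exponent_ci = ci,
               n_boot = n_boot, conf = conf),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(particle_id = character(), reason = character()),
    conditions = list(T_K = T_K, eta_Pa_s = eta_Pa_s,
                      A_correction = A_correction,
                      fit_max_lag_s = fit_max_lag_s)),
    class = "SizeBrightnessTable")
}
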