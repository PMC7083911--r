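#' Generate a synthetic nanosheet population
#'
#' Emulates an exfoliated nanosheet cohort in which height grows linearly
#' with lateral diameter and the smallest height corresponds to a ~1 nm
#' monolayer. Diameters are drawn log-uniformly over `diameter_range_nm`;
#' heights are `height_slope * diameter` with optional lognormal scatter,
#' then quantised to whole layers of thickness `monolayer_nm` (a layered
#' crystal has integer layer counts). The Cu2+ count per sheet follows the
#' areal density of luminescent centers in a single layer
#' (`sigma_cu_per_nm2`, default 3.8 ions per nm^2) over a disc of the given
#' diameter, times the layer count. Ground-truth brightness scales as a
#' power of diameter with multiplicative lognormal noise.
#'
#' @param n number of sheets.
#' @param diameter_range_nm length-2 interval, nm; equal endpoints force a
#'   fixed diameter.
#' @param height_slope linear height/diameter ratio (default 13/300 so the
#'   default range maps onto ~1-13 nm heights).
#' @param brightness_exponent power-law exponent of brightness vs diameter.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal brightness noise (0 = noise-free).
#' @param height_scatter_cv coefficient of variation of the lognormal
#'   scatter on height before layer quantisation.
#' @param monolayer_nm monolayer thickness, nm.
#' @param sigma_cu_per_nm2 areal density of Cu2+ ions in one layer, nm^-2.
#' @param brightness_scale prefactor of the brightness power law.
#' @param seed RNG seed (local; the caller's RNG state is preserved).
#' @return A `"SheetPopulation"` data frame with columns `diameter_nm`,
#'   `height_nm`, `n_layers`, `n_cu`, `true_brightness`.
#' @export
generate_sheet_population <- function(n,
                                      diameter_range_nm = c(20, 300),
                                      height_slope = 13 / 300,
                                      brightness_exponent = 0.5,
                                      noise_cv = 0.2,
                                      height_scatter_cv = 0.1,
                                      monolayer_nm = 1.0,
                                      sigma_cu_per_nm2 = 3.8,
                                      brightness_scale = 1.0,
                                      seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (length(diameter_range_nm) != 2L || any(diameter_range_nm <= 0) ||
      diameter_range_nm[2L] < diameter_range_nm[1L] ||
      diameter_range_nm[2L] > 1000) {
    stop("`diameter_range_nm` must be an interval within (0, 1000] nm",
         call. = FALSE)
  }
  if (brightness_exponent < 0) stop("`brightness_exponent` must be >= 0",
                                    call. = FALSE)
  .assert_scalar_pos(height_slope, "height_slope")
  .assert_scalar_pos(monolayer_nm, "monolayer_nm")

  local_seed(seed, {
    d <- exp(stats::runif(n, log(diameter_range_nm[1L]),
                          log(diameter_range_nm[2L])))
    h <- height_slope * d
    if (height_scatter_cv > 0) {
      sd_log <- sqrt(log(1 + height_scatter_cv^2))
      h <- h * stats::rlnorm(n, -sd_log^2 / 2, sd_log)
    }
    n_layers <- pmax(1L, as.integer(round(h / monolayer_nm)))
    height_nm <- n_layers * monolayer_nm
    area_nm2 <- pi * (d / 2)^2
    n_cu <- round(sigma_cu_per_nm2 * area_nm2 * n_layers)
    b <- brightness_scale * d^brightness_exponent
    if (noise_cv > 0) {
      sd_log <- sqrt(log(1 + noise_cv^2))
      b <- b * stats::rlnorm(n, -sd_log^2 / 2, sd_log)
    }
    out <- data.frame(diameter_nm = d, height_nm = height_nm,
                      n_layers = n_layers, n_cu = n_cu, true_brightness = b)
    attr(out, "params") <- list(
      diameter_range_nm = diameter_range_nm, height_slope = height_slope,
      brightness_exponent = brightness_exponent, noise_cv = noise_cv,
      height_scatter_cv = height_scatter_cv, monolayer_nm = monolayer_nm,
      sigma_cu_per_nm2 = sigma_cu_per_nm2, seed = seed)
    class(out) <- c("SheetPopulation", "data.frame")
    out
  })
}

#' Brownian-motion simulation parameters
#'
#' Bundles the physical conditions of a 2-D single-particle tracking
#' experiment. The diffusion coefficient follows Stokes-Einstein,
#' D = kB*T / (6 pi eta R), with an anisotropic sheet represented by its
#' sphere-equivalent Stokes radius; `D_um2_s` may be given directly to
#' bypass it. `viscosity_Pa_s = Inf` is the degenerate frozen-particle
#' limit (D = 0).
#'
#' @param stokes_radius_nm sphere-equivalent hydrodynamic radius, nm.
#' @param temperature_K absolute temperature, K.
#' @param viscosity_Pa_s dynamic viscosity, Pa s; `Inf` freezes the
#'   particle; `"auto"` computes it from [glycerol_viscosity()] at
#'   `glycerol_mass_fraction`.
#' @param frame_interval_s time between frames, s (0.125 s = 8 fps).
#' @param n_frames number of frames.
#' @param localization_sigma_um per-axis localisation noise SD, um.
#' @param active_burst `NULL` for purely thermal motion, or
#'   `list(rate = per-frame probability, scale_um = Laplace displacement
#'   scale)` adding sparse heavy-tailed displacement bursts.
#' @param glycerol_mass_fraction used only with `viscosity_Pa_s = "auto"`.
#' @param D_um2_s optional explicit diffusion coefficient, um^2/s.
#' @param seed RNG seed.
#' @return A `"MotionParams"` list with the implied `D_um2_s`.
#' @export
motion_params <- function(stokes_radius_nm = 50,
                          temperature_K = 295,
                          viscosity_Pa_s = 1.0,
                          frame_interval_s = 0.125,
                          n_frames = 1000,
                          localization_sigma_um = 0,
                          active_burst = NULL,
                          glycerol_mass_fraction = 1,
                          D_um2_s = NULL,
                          seed = NULL) {
  .assert_scalar_pos(stokes_radius_nm, "stokes_radius_nm")
  .assert_scalar_pos(temperature_K, "temperature_K")
  .assert_scalar_pos(frame_interval_s, "frame_interval_s")
  .assert_scalar_pos(n_frames, "n_frames")
  .assert_scalar_pos(localization_sigma_um, "localization_sigma_um",
                     strict = FALSE)
  if (identical(viscosity_Pa_s, "auto")) {
    viscosity_Pa_s <- glycerol_viscosity(temperature_K, glycerol_mass_fraction)
  }
  if (!is.numeric(viscosity_Pa_s) || viscosity_Pa_s <= 0) {
    stop("`viscosity_Pa_s` must be positive (Inf allowed)", call. = FALSE)
  }
  if (is.null(D_um2_s)) {
    ## kB*T/(6 pi eta R): R in m, D in m^2/s -> um^2/s
    D_um2_s <- if (is.infinite(viscosity_Pa_s)) 0 else
      .kB * temperature_K /
        (6 * pi * viscosity_Pa_s * stokes_radius_nm * 1e-9) * 1e12
  }
  if (!is.finite(D_um2_s) || D_um2_s < 0) {
    stop("implied diffusion coefficient must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.null(active_burst)) {
    if (!is.list(active_burst) ||
        !all(c("rate", "scale_um") %in% names(active_burst))) {
      stop("`active_burst` must be list(rate=, scale_um=)", call. = FALSE)
    }
  }
  structure(list(stokes_radius_nm = stokes_radius_nm,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 localization_sigma_um = localization_sigma_um,
                 active_burst = active_burst,
                 D_um2_s = D_um2_s,
                 seed = seed),
            class = "MotionParams")
}

## i.i.d. Laplace(0, scale) deviates
.rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Simulate a 2-D Brownian trajectory
#'
#' Positions are cumulative sums of i.i.d. Gaussian steps with per-axis
#' variance 2 * D * dt, plus i.i.d. localisation noise of SD
#' `localization_sigma_um` per axis, plus (optionally) sparse active
#' displacement bursts: with probability `rate` per step, each axis of that
#' step receives an extra Laplace-distributed displacement of scale
#' `scale_um`.
#'
#' @param params a [motion_params()] object.
#' @param particle_id identifier for the returned trajectory.
#' @return A [trajectory()] with `n_frames` points at times
#'   `0, dt, ..., (n-1)*dt`.
#' @export
simulate_trajectory <- function(params, particle_id = "sim1") {
  if (!inherits(params, "MotionParams")) {
    stop("`params` must come from motion_params()", call. = FALSE)
  }
  n <- params$n_frames
  dt <- params$frame_interval_s
  step_sd <- sqrt(2 * params$D_um2_s * dt)
  local_seed(params$seed, {
    dx <- stats::rnorm(n - 1L, 0, step_sd)
    dy <- stats::rnorm(n - 1L, 0, step_sd)
    if (!is.null(params$active_burst)) {
      hit <- stats::runif(n - 1L) < params$active_burst$rate
      nh <- sum(hit)
      if (nh > 0L) {
        dx[hit] <- dx[hit] + .rlaplace(nh, params$active_burst$scale_um)
        dy[hit] <- dy[hit] + .rlaplace(nh, params$active_burst$scale_um)
      }
    }
    x <- cumsum(c(0, dx))
    y <- cumsum(c(0, dy))
    if (params$localization_sigma_um > 0) {
      x <- x + stats::rnorm(n, 0, params$localization_sigma_um)
      y <- y + stats::rnorm(n, 0, params$localization_sigma_um)
    }
    trajectory(particle_id, t_s = (seq_len(n) - 1L) * dt, x_um = x, y_um = y)
  })
}

#' Render trajectories into a diffraction-limited synthetic movie
#'
#' Each particle appears as an integrated symmetric 2-D Gaussian of peak
#' amplitude `amplitudes[i]` and width `psf_sigma_px`: the flux
#' 2*pi*A*sigma^2 is distributed over pixels by the exact Gaussian integral
#' (erf differences), so with no noise the total frame intensity equals the
#' background plus the in-frame spot integrals. Positions whose centre
#' falls outside the frame are recorded in the `clipped` table (frame,
#' particle) and still rendered partially; nothing is silently dropped.
#'
#' @param trajectories list of [trajectory()] objects sharing one time base.
#' @param pixel_size_um physical pixel size, um/px.
#' @param psf_sigma_px PSF standard deviation, px.
#' @param amplitudes peak amplitude per trajectory (recycled if scalar),
#'   or an n_trajectories x n_frames matrix for per-frame modulation.
#' @param background constant background level added to every pixel.
#' @param noise_model `"none"`, `"poisson"`, or `"gaussian"`.
#' @param gaussian_sd SD of the additive Gaussian read noise (only for
#'   `noise_model = "gaussian"`).
#' @param dim_px `c(height, width)` in pixels; by default sized to contain
#'   all positions with a 5-sigma margin.
#' @param origin_um `c(x, y)` of the pixel-grid origin, um; defaults to
#'   place the trajectories with the same margin.
#' @param seed RNG seed for the noise.
#' @return A `"SyntheticMovie"`: list with `frames` (h x w x n array),
#'   acquisition metadata, `ground_truth` trajectories, and `clipped`.
#' @export
render_movie <- function(trajectories, pixel_size_um, psf_sigma_px = 2,
                         amplitudes = 100, background = 0,
                         noise_model = c("none", "poisson", "gaussian"),
                         gaussian_sd = 1, dim_px = NULL, origin_um = NULL,
                         seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  np <- length(trajectories)
  if (np < 1L) stop("need at least one trajectory", call. = FALSE)
  nf <- nrow(trajectories[[1L]])
  t0 <- trajectories[[1L]]$t_s
  for (tr in trajectories) {
    if (nrow(tr) != nf || max(abs(tr$t_s - t0)) > 1e-9) {
      stop("trajectories must share a common time base", call. = FALSE)
    }
  }
  amp <- if (is.matrix(amplitudes)) {
    if (nrow(amplitudes) != np || ncol(amplitudes) != nf) {
      stop("amplitude matrix must be n_trajectories x n_frames", call. = FALSE)
    }
    amplitudes
  } else {
    matrix(rep_len(amplitudes, np), nrow = np, ncol = nf)
  }
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  .assert_scalar_pos(psf_sigma_px, "psf_sigma_px")

  margin_px <- 5 * psf_sigma_px
  xs <- unlist(lapply(trajectories, `[[`, "x_um"))
  ys <- unlist(lapply(trajectories, `[[`, "y_um"))
  if (is.null(origin_um)) {
    origin_um <- c(min(xs) - margin_px * pixel_size_um,
                   min(ys) - margin_px * pixel_size_um)
  }
  if (is.null(dim_px)) {
    w <- ceiling((max(xs) - origin_um[1L]) / pixel_size_um + margin_px) + 1L
    h <- ceiling((max(ys) - origin_um[2L]) / pixel_size_um + margin_px) + 1L
    dim_px <- c(h, w)
  }
  h <- as.integer(dim_px[1L]); w <- as.integer(dim_px[2L])

  frames <- array(background, dim = c(h, w, nf))
  clipped <- list()
  ## pixel i (1-based) spans [i-1.5, i-0.5]*px around centre coordinate
  ## x_px = (x_um - origin)/px measured in 0-based pixel-centre units
  for (p in seq_len(np)) {
    tr <- trajectories[[p]]
    flux_f <- 2 * pi * amp[p, ] * psf_sigma_px^2
    x_px <- (tr$x_um - origin_um[1L]) / pixel_size_um
    y_px <- (tr$y_um - origin_um[2L]) / pixel_size_um
    out_of_frame <- x_px < 0 | x_px > (w - 1L) | y_px < 0 | y_px > (h - 1L)
    if (any(out_of_frame)) {
      clipped[[length(clipped) + 1L]] <-
        data.frame(particle = p, frame = which(out_of_frame))
    }
    r <- ceiling(4 * psf_sigma_px)
    for (f in seq_len(nf)) {
      cx <- x_px[f]; cy <- y_px[f]
      x_lo <- max(1L, floor(cx + 1 - r)); x_hi <- min(w, ceiling(cx + 1 + r))
      y_lo <- max(1L, floor(cy + 1 - r)); y_hi <- min(h, ceiling(cy + 1 + r))
      if (x_lo > x_hi || y_lo > y_hi) next  # fully outside the frame
      ix <- x_lo:x_hi; iy <- y_lo:y_hi
      ## integral of the unit-mass Gaussian over each pixel row/column;
      ## 1-based pixel i has 0-based centre i-1 and spans [i-1.5, i-0.5]
      px_x <- stats::pnorm(ix - 0.5, cx, psf_sigma_px) -
              stats::pnorm(ix - 1.5, cx, psf_sigma_px)
      px_y <- stats::pnorm(iy - 0.5, cy, psf_sigma_px) -
              stats::pnorm(iy - 1.5, cy, psf_sigma_px)
      frames[iy, ix, f] <- frames[iy, ix, f] + flux_f[f] * outer(px_y, px_x)
    }
  }
  frames <- local_seed(seed, switch(noise_model,
    none = frames,
    poisson = array(stats::rpois(length(frames), frames), dim = dim(frames)),
    gaussian = frames + array(stats::rnorm(length(frames), 0, gaussian_sd),
                              dim = dim(frames))
  ))
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 psf_sigma_px = psf_sigma_px, background_level = background,
                 noise_model = noise_model, amplitudes = amplitudes,
                 origin_um = origin_um,
                 frame_interval_s = if (nf > 1L) t0[2L] - t0[1L] else NA_real_,
                 ground_truth = trajectories,
                 clipped = if (length(clipped)) do.call(rbind, clipped) else
                   data.frame(particle = integer(), frame = integer()),
                 seed = seed),
            class = "SyntheticMovie")
}

#' @export
print.SyntheticMovie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<SyntheticMovie %dx%d px, %d frames, %d particles, noise=%s>\n",
              d[1L], d[2L], d[3L], length(x$ground_truth), x$noise_model))
  invisible(x)
}

#' Simulate an excitation-power saturation sweep
#'
#' Detected counts follow the fluorescence-saturation law
#' I = I_sat * P / (P + P_sat), scaled by the overall detection efficiency
#' and integration time, with optional Poisson shot noise. The power is
#' stepped up and then down by default, as in a hysteresis-checked
#' measurement.
#'
#' @param I_sat_per_s emitted photon rate at saturation, photons/s.
#' @param P_sat_uW saturation power, uW.
#' @param powers_uW excitation powers, uW (one sweep direction).
#' @param integration_s integration time per point, s.
#' @param efficiency a [detection_efficiency()]; its `overall` fraction
#'   scales emitted to detected photons.
#' @param noise `"poisson"` or `"none"`.
#' @param directions `"both"` (up then down), `"up"`, or `"down"`.
#' @param seed RNG seed.
#' @return A `"SaturationCurve"` data frame with columns `P_exc_uW`,
#'   `detected_counts_per_s`, `direction`; ground-truth parameters and the
#'   efficiency ride along as attributes.
#' @export
simulate_saturation_sweep <- function(I_sat_per_s, P_sat_uW, powers_uW,
                                      integration_s = 1,
                                      efficiency = detection_efficiency(1, 1, 1),
                                      noise = c("poisson", "none"),
                                      directions = c("both", "up", "down"),
                                      seed = NULL) {
  noise <- match.arg(noise)
  directions <- match.arg(directions)
  .assert_scalar_pos(I_sat_per_s, "I_sat_per_s")
  .assert_scalar_pos(P_sat_uW, "P_sat_uW")
  .assert_scalar_pos(integration_s, "integration_s")
  if (any(powers_uW < 0)) stop("powers must be nonnegative", call. = FALSE)
  P <- switch(directions,
              both = c(sort(powers_uW), sort(powers_uW, decreasing = TRUE)),
              up = sort(powers_uW),
              down = sort(powers_uW, decreasing = TRUE))
  dir <- switch(directions,
                both = rep(c("up", "down"), each = length(powers_uW)),
                up = rep("up", length(P)),
                down = rep("down", length(P)))
  expected <- efficiency$overall * I_sat_per_s * P / (P + P_sat_uW) *
    integration_s
  counts <- local_seed(seed, switch(noise,
    none = expected,
    poisson = stats::rpois(length(expected), expected)))
  out <- data.frame(P_exc_uW = P,
                    detected_counts_per_s = counts / integration_s,
                    direction = dir)
  attr(out, "truth") <- list(I_sat_per_s = I_sat_per_s, P_sat_uW = P_sat_uW)
  attr(out, "integration_s") <- integration_s
  attr(out, "efficiency") <- efficiency
  attr(out, "seed") <- seed
  class(out) <- c("SaturationCurve", "data.frame")
  out
}

#' Generate a synthetic nucleus map
#'
#' Nuclei are laid out on a jittered hexagonal grid, emulating the regular
#' 2-D nuclear array beneath the plasma membrane of a syncytial embryo.
#' Each nucleus boundary is a regular polygon (>= 24 vertices)
#' approximating a circle; maps are regenerated (bounded retries) if the
#' jitter makes any pair overlap.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param nucleus_radius_um nucleus radius, um.
#' @param spacing_um centre-to-centre grid spacing, um; must exceed twice
#'   the radius.
#' @param jitter_um uniform per-axis jitter half-width, um.
#' @param n_vertices vertices per polygon (>= 24).
#' @param max_retries jitter retries before giving up.
#' @param seed RNG seed.
#' @return A `"NucleusMap"`: list with `polygons` (list of n x 2 vertex
#'   matrices, open rings), `centers`, `radius_um`.
#' @export
generate_nucleus_map <- function(n_rows, n_cols, nucleus_radius_um = 2.5,
                                 spacing_um = 7, jitter_um = 0,
                                 n_vertices = 24, max_retries = 20,
                                 seed = NULL) {
  .assert_scalar_pos(n_rows, "n_rows"); .assert_scalar_pos(n_cols, "n_cols")
  .assert_scalar_pos(nucleus_radius_um, "nucleus_radius_um")
  if (spacing_um <= 2 * nucleus_radius_um) {
    stop("`spacing_um` must exceed twice the nucleus radius", call. = FALSE)
  }
  if (n_vertices < 24) stop("`n_vertices` must be >= 24", call. = FALSE)
  base <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  cx0 <- (base$col - 1) * spacing_um + ifelse(base$row %% 2 == 0,
                                              spacing_um / 2, 0)
  cy0 <- (base$row - 1) * spacing_um * sqrt(3) / 2
  n <- nrow(base)
  local_seed(seed, {
    for (attempt in seq_len(max_retries + 1L)) {
      cx <- cx0; cy <- cy0
      if (jitter_um > 0) {
        cx <- cx + stats::runif(n, -jitter_um, jitter_um)
        cy <- cy + stats::runif(n, -jitter_um, jitter_um)
      }
      if (n == 1L) break
      dmin <- min(stats::dist(cbind(cx, cy)))
      if (dmin > 2 * nucleus_radius_um) break
      if (attempt == max_retries + 1L) {
        stop("could not place non-overlapping nuclei within retry budget",
             call. = FALSE)
      }
    }
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    polys <- lapply(seq_len(n), function(i) {
      cbind(x_um = cx[i] + nucleus_radius_um * cos(th),
            y_um = cy[i] + nucleus_radius_um * sin(th))
    })
    structure(list(polygons = polys, centers = cbind(x_um = cx, y_um = cy),
                   radius_um = nucleus_radius_um, seed = seed),
              class = "NucleusMap")
  })
}
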