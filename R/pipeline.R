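#' Pipeline configuration
#'
#' Collects every stage parameter of the three end-to-end scenarios with
#' defaults matching the study conditions: glycerol sizing (8 fps, 1000
#' frames, MSD fit window 25 s, min trajectory length 300), embryo
#' microrheology (10 fps, 60 s, min length 200, Van Hove lag 0.1 s,
#' Gaussian window +/- 0.03 um), photophysics (lifetime 100 us, quantum
#' yield 0.1, 3.8 Cu2+ per nm^2, efficiency chain 0.70 x 0.50 x 0.05).
#' Tracking defaults: blob diameter 11 px, search range 9 px, memory 300
#' frames. The anisotropy correction defaults to A = 1.49.
#'
#' @param scenario `"glycerol"`, `"embryo"`, or `"photophysics"`.
#' @param seed integer master seed for the run.
#' @param ... overrides for any default parameter (unknown names error).
#' @return A `"PipelineConfig"` list; `defaults_overridden` names the
#'   parameters the user set, for provenance logging.
#' @export
pipeline_config <- function(scenario = c("glycerol", "embryo", "photophysics"),
                            seed = 1, ...) {
  scenario <- match.arg(scenario)
  defaults <- list(
    # acquisition
    fps = if (scenario == "embryo") 10 else 8,
    n_frames = if (scenario == "embryo") 600 else 1000,
    pixel_size_um = 0.1,
    # tracking
    blob_diameter_px = 11, search_range_px = 9, memory_frames = 300,
    min_length = if (scenario == "embryo") 200 else 300,
    min_mass = 0, percentile_threshold = 64,
    # sizing
    max_lag_s = 25, A_correction = 1.49, temperature_K = 295,
    viscosity_Pa_s = 1.0,
    # van hove
    vh_lag_s = 0.1, vh_window_um = c(-0.03, 0.03), vh_bin_width_um = 0.005,
    # photophysics
    lifetime_s = 1e-4, quantum_yield = 0.1, sigma_cu_per_nm2 = 3.8,
    collection = 0.70, optics_transmission = 0.50, detector_qe = 0.05,
    # synthetic-input scale
    n_particles = if (scenario == "embryo") 8 else 10,
    n_sweeps = 5, sweep_powers_uW = c(1, 2, 5, 10, 20, 50, 75, 100,
                                      150, 200, 350, 500),
    I_sat_per_s = 5e5, P_sat_uW = 200, integration_s = 1,
    radius_range_nm = c(25, 200),
    active_burst = NULL)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  # merge by name, preserving NULL-valued settings (e.g. active_burst)
  for (nm in names(user)) cfg[nm] <- list(user[[nm]])
  cfg$scenario <- scenario
  cfg$seed <- as.integer(seed)
  cfg$defaults_overridden <- names(user)
  structure(cfg, class = "PipelineConfig")
}

#' Serialise / restore a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @return `path` / the restored `"PipelineConfig"`.
#' @export
write_pipeline_config <- function(config, path) {
  .atomic_write(function(tmp) {
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }, path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- raw$scenario
  seed <- raw$seed
  overridden <- raw$defaults_overridden
  raw$scenario <- NULL; raw$seed <- NULL; raw$defaults_overridden <- NULL
  cfg <- do.call(pipeline_config, c(list(scenario = scenario, seed = seed),
                                    raw))
  cfg$defaults_overridden <- overridden %||% character()
  cfg
}

#' Run an end-to-end scenario
#'
#' Executes the stage chain of the configured scenario on synthetic inputs
#' generated from the config seed (or on user-supplied inputs), writes all
#' intermediate artifacts plus a JSON summary and a provenance log under
#' `out_dir`, and returns the result bundle. Scenarios:
#' \describe{
#'   \item{glycerol}{simulate nanosheets diffusing in glycerol, render a
#'     movie, detect + link, MSD-size every trajectory and correlate size
#'     with brightness.}
#'   \item{embryo}{simulate thermal (or burst-active) motion among a
#'     nucleus array, then Van Hove analysis and nucleus-proximity
#'     partitioning.}
#'   \item{photophysics}{simulate saturation sweeps, fit the saturation
#'     law, count luminescent centers.}
#' }
#'
#' @param config a [pipeline_config()].
#' @param inputs optional named list of paths (`trajectories` CSV,
#'   `movie` TIFF, `nucleus_map` CSV, `saturation` CSV) to analyse instead
#'   of synthesising.
#' @param out_dir output directory (`NULL` = no files written).
#' @return A list with the scenario's result objects and `summary` (the
#'   content of the JSON summary).
#' @export
run_pipeline <- function(config, inputs = NULL, out_dir = NULL) {
  if (!inherits(config, "PipelineConfig")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  for (p in names(inputs)) {
    if (!file.exists(inputs[[p]])) {
      stop("input file for `", p, "` does not exist: ", inputs[[p]],
           call. = FALSE)
    }
  }
  res <- switch(config$scenario,
                glycerol = .run_glycerol(config, inputs),
                embryo = .run_embryo(config, inputs),
                photophysics = .run_photophysics(config, inputs))
  res$summary$scenario <- config$scenario
  res$summary$seed <- config$seed
  res$summary$defaults_overridden <- config$defaults_overridden
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.json"))
    if (!is.null(res$trajectories)) {
      write_trajectories_csv(res$trajectories,
                             file.path(out_dir, "trajectories.csv"))
    }
    .atomic_write(function(tmp) {
      jsonlite::write_json(res$summary, tmp, auto_unbox = TRUE, digits = NA,
                           null = "null")
    }, file.path(out_dir, "summary.json"))
  }
  res
}

.run_glycerol <- function(config, inputs) {
  dt <- 1 / config$fps
  if (!is.null(inputs$trajectories)) {
    trajs <- read_trajectories_csv(inputs$trajectories)
  } else if (!is.null(inputs$movie)) {
    mv <- read_movie_tiff(inputs$movie)
    trajs <- track_movie(mv$frames,
                         link_params(config$search_range_px,
                                     config$memory_frames, config$min_length,
                                     config$blob_diameter_px),
                         pixel_size_um = mv$pixel_size_um,
                         frame_interval_s = mv$frame_interval_s,
                         min_mass = config$min_mass,
                         percentile_threshold = config$percentile_threshold)
  } else {
    sheets <- generate_sheet_population(config$n_particles,
                                        seed = config$seed)
    radii <- pmax(pmin(sheets$diameter_nm / 2, config$radius_range_nm[2L]),
                  config$radius_range_nm[1L])
    raw <- lapply(seq_len(config$n_particles), function(i) {
      ## a sheet of hydrodynamic radius r diffuses like a sphere of
      ## Stokes radius r / A, so the sizing chain recovers R_hydro = r
      simulate_trajectory(motion_params(
        stokes_radius_nm = radii[i] / config$A_correction,
        temperature_K = config$temperature_K,
        viscosity_Pa_s = config$viscosity_Pa_s,
        frame_interval_s = dt, n_frames = config$n_frames,
        seed = config$seed + i), particle_id = paste0("p", i))
    })
    for (i in seq_along(raw)) {
      raw[[i]]$mass <- 2 * pi * sheets$true_brightness[i] * 2^2
    }
    trajs <- raw
  }
  sbt <- size_brightness_correlation(trajs, T_K = config$temperature_K,
                                     eta_Pa_s = config$viscosity_Pa_s,
                                     A_correction = config$A_correction,
                                     fit_max_lag_s = config$max_lag_s,
                                     seed = config$seed)
  rho <- stats::cor(sbt$table$R_hydro_nm, sbt$table$max_mass,
                    method = "spearman")
  list(trajectories = trajs, size_brightness = sbt,
       summary = list(n_trajectories = length(trajs),
                      n_sized = nrow(sbt$table),
                      powerlaw_exponent = sbt$fit$exponent,
                      powerlaw_exponent_ci = sbt$fit$exponent_ci,
                      spearman_size_brightness = rho,
                      median_R_hydro_nm = stats::median(sbt$table$R_hydro_nm)))
}

.run_embryo <- function(config, inputs) {
  dt <- 1 / config$fps
  map <- if (!is.null(inputs$nucleus_map)) {
    read_nucleus_map_csv(inputs$nucleus_map)
  } else {
    generate_nucleus_map(4, 4, nucleus_radius_um = 2.5, spacing_um = 7,
                         jitter_um = 0.5, seed = config$seed)
  }
  if (!is.null(inputs$trajectories)) {
    trajs <- read_trajectories_csv(inputs$trajectories)
  } else {
    span <- apply(map$centers, 2L, range)
    trajs <- local_seed(config$seed + 99L, {
      lapply(seq_len(config$n_particles), function(i) {
        tr <- simulate_trajectory(motion_params(
          D_um2_s = 1e-3, frame_interval_s = dt, n_frames = config$n_frames,
          active_burst = config$active_burst,
          seed = config$seed + 100L + i), particle_id = paste0("e", i))
        ## park each walker at a distinct spot inside the nucleus field
        tr$x_um <- tr$x_um + stats::runif(1, span[1L, 1L], span[2L, 1L])
        tr$y_um <- tr$y_um + stats::runif(1, span[1L, 2L], span[2L, 2L])
        tr
      })
    })
  }
  vh <- compute_van_hove(trajs, lag_s = config$vh_lag_s,
                         bin_width_um = config$vh_bin_width_um,
                         gaussian_window_um = config$vh_window_um,
                         seed = config$seed)
  part <- partition_by_proximity(trajs, map, lag_s = config$vh_lag_s,
                                 bin_width_um = config$vh_bin_width_um,
                                 gaussian_window_um = config$vh_window_um,
                                 seed = config$seed)
  list(trajectories = trajs, nucleus_map = map, van_hove = vh,
       partition = part,
       summary = list(n_trajectories = length(trajs),
                      vh_sigma_um = vh$gaussian_fit$sigma_um,
                      tail_excess = vh$tail_excess,
                      excess_kurtosis = vh$excess_kurtosis,
                      active_processes_detected = vh$active_processes_detected,
                      proximity_threshold_um = part$threshold_um,
                      variance_ratio = part$comparison$variance_ratio,
                      wilcox_p = part$comparison$wilcox_p,
                      underpowered = part$comparison$underpowered))
}

.run_photophysics <- function(config, inputs) {
  eff <- detection_efficiency(config$collection, config$optics_transmission,
                              config$detector_qe)
  curves <- if (!is.null(inputs$saturation)) {
    list(read_saturation_csv(inputs$saturation))
  } else {
    lapply(seq_len(config$n_sweeps), function(i) {
      simulate_saturation_sweep(config$I_sat_per_s, config$P_sat_uW,
                                config$sweep_powers_uW,
                                integration_s = config$integration_s,
                                efficiency = eff, seed = config$seed + i)
    })
  }
  fits <- lapply(curves, fit_saturation, efficiency = eff)
  ests <- lapply(fits, count_luminescent_centers,
                 lifetime_s = config$lifetime_s,
                 quantum_yield = config$quantum_yield,
                 sigma_cu_per_nm2 = config$sigma_cu_per_nm2)
  list(curves = curves, fits = fits, estimates = ests,
       summary = list(
         n_curves = length(curves),
         I_sat_per_s = vapply(fits, `[[`, numeric(1), "I_sat_per_s"),
         P_sat_uW = vapply(fits, `[[`, numeric(1), "P_sat_uW"),
         N_centers = vapply(ests, `[[`, numeric(1), "N_centers"),
         monolayer_side_nm = vapply(ests, `[[`, numeric(1),
                                    "monolayer_side_nm")))
}
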