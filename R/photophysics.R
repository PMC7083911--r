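#' Detection-efficiency chain of the confocal photon-counting setup
#'
#' The overall fraction of emitted photons that register on the detector
#' is the product of the objective's average collection efficiency for
#' randomly oriented emission dipoles (default 0.70), the transmissivity
#' of the optical path (default 0.50), and the detector quantum efficiency
#' in the emission band (default 0.05 for a single-photon avalanche diode
#' near 910 nm). Defaults give overall = 0.0175.
#'
#' @param collection objective collection efficiency, in (0, 1].
#' @param optics_transmission optical-path transmissivity, in (0, 1].
#' @param detector_qe detector quantum efficiency, in (0, 1].
#' @return A `"DetectionEfficiency"` list with the three factors and
#'   `overall` = their exact product.
#' @export
detection_efficiency <- function(collection = 0.70, optics_transmission = 0.50,
                                 detector_qe = 0.05) {
  for (v in list(collection = collection,
                 optics_transmission = optics_transmission,
                 detector_qe = detector_qe)) {
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("efficiencies must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(collection = collection,
                 optics_transmission = optics_transmission,
                 detector_qe = detector_qe,
                 overall = collection * optics_transmission * detector_qe),
            class = "DetectionEfficiency")
}

#' Fit the fluorescence saturation law to a power sweep
#'
#' Detected rates are first divided by the overall detection efficiency
#' (so the fitted amplitude is the *emitted* photon rate), then the
#' saturation law I = I_sat * P / (P + P_sat) is fitted by
#' Levenberg-Marquardt nonlinear least squares. Initialisation:
#' I_sat = 2 * max(I), P_sat = median(P); relative convergence tolerance
#' 1e-10. Up- and down-sweep points are pooled into one fit; a hysteresis
#' diagnostic (maximum absolute up-vs-down rate difference at matched
#' powers) is reported, and `plateau_reached` records whether the maximum
#' excitation power exceeded the fitted saturation power.
#'
#' @param curve a `"SaturationCurve"` (data frame with `P_exc_uW`,
#'   `detected_counts_per_s`, optional `direction`).
#' @param efficiency a [detection_efficiency()]; defaults to the one the
#'   curve was simulated with, else to unit efficiency.
#' @return A `"SaturationFit"` list: `I_sat_per_s`, `P_sat_uW`,
#'   `covariance` (2x2), `residual_norm`, `plateau_reached`,
#'   `hysteresis_per_s`.
#' @export
fit_saturation <- function(curve, efficiency = NULL) {
  if (!is.data.frame(curve) ||
      !all(c("P_exc_uW", "detected_counts_per_s") %in% names(curve))) {
    stop("`curve` must have columns P_exc_uW and detected_counts_per_s",
         call. = FALSE)
  }
  if (length(unique(curve$P_exc_uW)) < 4L) {
    stop("need at least 4 distinct excitation powers", call. = FALSE)
  }
  if (all(curve$detected_counts_per_s == 0)) {
    stop("all counts are zero; nothing to fit", call. = FALSE)
  }
  efficiency <- efficiency %||% attr(curve, "efficiency") %||%
    detection_efficiency(1, 1, 1)
  P <- curve$P_exc_uW
  I <- curve$detected_counts_per_s / efficiency$overall
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ Isat * P / (P + Psat),
                      start = list(Isat = 2 * max(I), Psat = stats::median(P)),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
    error = function(e) stop("saturation fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  if (any(cf <= 0)) {
    stop(sprintf(
      "saturation fit produced non-positive parameters (I_sat=%.3g, P_sat=%.3g)",
      cf[["Isat"]], cf[["Psat"]]), call. = FALSE)
  }
  hyst <- NA_real_
  if ("direction" %in% names(curve) && all(c("up", "down") %in% curve$direction)) {
    up <- tapply(I[curve$direction == "up"], P[curve$direction == "up"], mean)
    dn <- tapply(I[curve$direction == "down"], P[curve$direction == "down"], mean)
    common <- intersect(names(up), names(dn))
    if (length(common) > 0L) hyst <- max(abs(up[common] - dn[common]))
  }
  structure(list(I_sat_per_s = cf[["Isat"]], P_sat_uW = cf[["Psat"]],
                 covariance = stats::vcov(fit),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 plateau_reached = max(P) >= cf[["Psat"]],
                 hysteresis_per_s = hyst,
                 efficiency = efficiency),
            class = "SaturationFit")
}

#' Estimate the number of luminescent centers from a saturation fit
#'
#' Converts the saturation emission rate into a count of independently
#' emitting Cu2+ centers: N = I_sat * tau / Phi, where tau is the
#' excited-state lifetime (default 100 us) and Phi the quantum yield
#' (default 0.1). The equivalent monolayer sheet size assumes a square
#' single-layer sheet with `sigma_cu_per_nm2` centers per nm^2 (default
#' 3.8): side = sqrt(N / sigma). Both the unrounded side and its
#' nearest-nm rounding are reported.
#'
#' @param fit a `"SaturationFit"` from [fit_saturation()], or a numeric
#'   emitted saturation rate in photons/s.
#' @param lifetime_s excited-state lifetime, s.
#' @param quantum_yield emission quantum yield, in (0, 1].
#' @param sigma_cu_per_nm2 areal density of centers in one layer, nm^-2.
#' @return An `"EmitterEstimate"` list: `N_centers`, `lifetime_s`,
#'   `quantum_yield`, `sigma_cu_per_nm2`, `monolayer_side_nm`,
#'   `monolayer_side_nm_rounded`.
#' @export
count_luminescent_centers <- function(fit, lifetime_s = 1.0e-4,
                                      quantum_yield = 0.1,
                                      sigma_cu_per_nm2 = 3.8) {
  I_sat <- if (inherits(fit, "SaturationFit")) fit$I_sat_per_s else fit
  .assert_scalar_pos(I_sat, "I_sat"); .assert_scalar_pos(lifetime_s, "lifetime_s")
  if (quantum_yield <= 0 || quantum_yield > 1) {
    stop("`quantum_yield` must be in (0, 1]", call. = FALSE)
  }
  .assert_scalar_pos(sigma_cu_per_nm2, "sigma_cu_per_nm2")
  N <- I_sat * lifetime_s / quantum_yield
  side <- sqrt(N / sigma_cu_per_nm2)
  structure(list(N_centers = N, lifetime_s = lifetime_s,
                 quantum_yield = quantum_yield,
                 sigma_cu_per_nm2 = sigma_cu_per_nm2,
                 monolayer_side_nm = side,
                 monolayer_side_nm_rounded = round(side)),
            class = "EmitterEstimate")
}

#' @export
print.EmitterEstimate <- function(x, ...) {
  cat(sprintf(
    "<EmitterEstimate: N = %.4g centers (tau = %.3g s, Phi = %.3g); square monolayer side %.3g nm (~%d nm)>\n",
    x$N_centers, x$lifetime_s, x$quantum_yield, x$monolayer_side_nm,
    x$monolayer_side_nm_rounded))
  invisible(x)
}

#' Photostability statistics of an intensity time trace
#'
#' Normalises the trace to its initial value, fits a single-exponential
#' decay I(t) = A * exp(-k * t), and classifies the trace as showing "no
#' detectable bleaching" when the 95% confidence interval of the decay
#' rate covers zero.
#'
#' @param intensity per-frame mean intensities (>= 10 points).
#' @param t_s acquisition times, s.
#' @return A list: `normalized` trace, `fractional_loss`
#'   (1 - last/first), `decay_rate_per_s`, `rate_ci`, `no_detectable_bleaching`.
#' @export
bleaching_trace_stats <- function(intensity, t_s) {
  if (length(intensity) < 10L) stop("need >= 10 points", call. = FALSE)
  if (length(intensity) != length(t_s)) stop("length mismatch", call. = FALSE)
  if (intensity[1L] <= 0) stop("initial intensity must be positive",
                               call. = FALSE)
  y <- intensity / intensity[1L]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t_s),
                      start = list(A = 1, k = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    se_k <- tryCatch(sqrt(stats::vcov(fit)[2L, 2L]),
                     error = function(e) NA_real_)
  } else {
    ## an exactly flat trace makes the nonlinear gradient singular;
    ## the log-linear fit is then exact and gives the same rate
    lf <- stats::lm(log(pmax(y, .Machine$double.eps)) ~ t_s)
    cf <- c(A = exp(unname(stats::coef(lf)[1L])),
            k = -unname(stats::coef(lf)[2L]))
    se_k <- summary(lf)$coefficients[2L, 2L]
  }
  ci <- cf[["k"]] + c(-1, 1) * stats::qnorm(0.975) * se_k
  ## a rate whose CI covers zero -- or one so small that the implied loss
  ## over the whole trace is below numerical precision -- means no bleaching
  negligible <- abs(cf[["k"]]) * diff(range(t_s)) < 1e-8
  list(normalized = y,
       fractional_loss = 1 - y[length(y)],
       decay_rate_per_s = cf[["k"]],
       rate_ci = ci,
       no_detectable_bleaching =
         (is.finite(ci[1L]) && ci[1L] <= 0 && ci[2L] >= 0) || negligible)
}
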