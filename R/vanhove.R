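#' Build a nucleus map from polygon vertex rings
#'
#' For measured nucleus perimeters (or any hand-built map): each polygon
#' is an n x 2 matrix of (x_um, y_um) vertices in order, ring closure
#' implied.
#'
#' @param polygons list of n x 2 vertex matrices (n >= 3 each).
#' @return A `"NucleusMap"`.
#' @export
nucleus_map <- function(polygons) {
  if (!is.list(polygons) || length(polygons) == 0L) {
    stop("`polygons` must be a non-empty list", call. = FALSE)
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop("each polygon needs >= 3 (x, y) vertices", call. = FALSE)
    }
    p
  })
  structure(list(polygons = polygons,
                 centers = t(vapply(polygons, colMeans, numeric(2))),
                 radius_um = NA_real_, seed = NULL),
            class = "NucleusMap")
}

#' Instantaneous speeds along a trajectory
#'
#' speed_i = |r(t_i + lag) - r(t_i)| / lag at every point where the lagged
#' position exists. The lag must be an integer multiple of the frame
#' interval.
#'
#' @param traj a uniformly sampled [trajectory()].
#' @param lag_s lag time, s (default 0.1).
#' @return Numeric vector of speeds, um/s, length `n - lag/dt`.
#' @export
instantaneous_velocity <- function(traj, lag_s = 0.1) {
  if (!inherits(traj, "Trajectory")) stop("`traj` must be a Trajectory")
  dt <- .frame_interval(traj$t_s)
  k <- lag_s / dt
  if (abs(k - round(k)) > 1e-6) {
    stop("`lag_s` must be an integer multiple of the frame interval",
         call. = FALSE)
  }
  k <- as.integer(round(k))
  n <- nrow(traj)
  if (k < 1L || k >= n) stop("lag outside the trajectory span", call. = FALSE)
  dx <- traj$x_um[(k + 1L):n] - traj$x_um[1L:(n - k)]
  dy <- traj$y_um[(k + 1L):n] - traj$y_um[1L:(n - k)]
  sqrt(dx^2 + dy^2) / lag_s
}

## minimum distance from points (n x 2) to one polygon boundary (open ring)
.dist_to_ring <- function(px, py, ring) {
  vx <- ring[, 1L]; vy <- ring[, 2L]
  nx <- c(vx[-1L], vx[1L]); ny <- c(vy[-1L], vy[1L])
  ex <- nx - vx; ey <- ny - vy
  el2 <- ex^2 + ey^2
  best <- rep(Inf, length(px))
  for (e in seq_along(vx)) {
    tpar <- ((px - vx[e]) * ex[e] + (py - vy[e]) * ey[e]) /
      max(el2[e], .Machine$double.eps)
    tpar <- pmin(pmax(tpar, 0), 1)
    qx <- vx[e] + tpar * ex[e]; qy <- vy[e] + tpar * ey[e]
    best <- pmin(best, sqrt((px - qx)^2 + (py - qy)^2))
  }
  best
}

#' Minimum distance from points to the nearest nucleus border
#'
#' Unsigned Euclidean distance to the closest polygon boundary of the map:
#' points inside a nucleus also receive their distance to the border.
#'
#' @param points an n x 2 matrix / data frame of (x, y) in um, or a
#'   length-2 vector for one point.
#' @param map a `"NucleusMap"` (see [generate_nucleus_map()] or
#'   [read_nucleus_map_csv()]).
#' @return Numeric vector of distances, um.
#' @export
distance_to_nuclei <- function(points, map) {
  if (!inherits(map, "NucleusMap") || length(map$polygons) == 0L) {
    stop("`map` must be a non-empty NucleusMap", call. = FALSE)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  best <- rep(Inf, nrow(points))
  for (ring in map$polygons) {
    best <- pmin(best, .dist_to_ring(points[, 1L], points[, 2L], ring))
  }
  best
}

## pool per-axis displacements at integer-lag k across trajectories;
## also returns the start-point coordinates of each displacement
.pooled_displacements <- function(trajs, lag_s) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  dx <- list(); sx <- list(); sy <- list()
  for (tr in trajs) {
    if (nrow(tr) < 2L) next
    dt <- .frame_interval(tr$t_s)
    k <- lag_s / dt
    if (abs(k - round(k)) > 1e-6) {
      stop("`lag_s` must be an integer multiple of the frame interval",
           call. = FALSE)
    }
    k <- as.integer(round(k))
    n <- nrow(tr)
    if (k < 1L || k >= n) next
    i0 <- 1L:(n - k)
    dx[[length(dx) + 1L]] <-
      c(tr$x_um[i0 + k] - tr$x_um[i0], tr$y_um[i0 + k] - tr$y_um[i0])
    sx[[length(sx) + 1L]] <- rep(tr$x_um[i0], 2L)
    sy[[length(sy) + 1L]] <- rep(tr$y_um[i0], 2L)
  }
  list(d = unlist(dx) %||% numeric(),
       x0 = unlist(sx) %||% numeric(),
       y0 = unlist(sy) %||% numeric())
}

.vh_histogram <- function(d, bin_width_um) {
  m <- max(abs(d), bin_width_um)
  nb <- ceiling(m / bin_width_um + 0.5)
  ## edges symmetric about zero, bin centres at -nb*bw, ..., 0, ..., nb*bw
  edges <- (seq(-nb, nb + 1L) - 0.5) * bin_width_um
  counts <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
  list(edges = edges, centers = (edges[-1L] + edges[-length(edges)]) / 2,
       prob = counts / length(d))
}

.vh_gauss_fit <- function(centers, prob, window) {
  inw <- centers >= window[1L] - 1e-12 & centers <= window[2L] + 1e-12
  if (sum(inw) < 3L) {
    stop("Gaussian window contains fewer than 3 histogram bins",
         call. = FALSE)
  }
  xc <- centers[inw]; pc <- prob[inw]
  s0 <- sqrt(max(sum(pc * xc^2) / max(sum(pc), 1e-12), 1e-12))
  fit <- minpack.lm::nlsLM(pc ~ a * exp(-xc^2 / (2 * s^2)),
                           start = list(a = max(pc), s = s0),
                           lower = c(0, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(amplitude = cf[["a"]], sigma_um = cf[["s"]], in_window = inw)
}

.vh_tail_excess <- function(centers, prob, gfit, window) {
  out <- !(centers >= window[1L] - 1e-12 & centers <= window[2L] + 1e-12)
  obs <- sum(prob[out])
  pred <- sum(gfit$amplitude * exp(-centers[out]^2 / (2 * gfit$sigma_um^2)))
  max(obs - pred, 0)
}

#' Van Hove displacement analysis
#'
#' Pools per-axis (x and y) displacements at one lag across trajectories,
#' builds a symmetric probability histogram, fits a Gaussian to the
#' central bins (unweighted least squares on histogram heights within
#' `gaussian_window_um`), and quantifies the non-Gaussian tails: the
#' `tail_excess` is the observed probability mass outside the window minus
#' the fitted Gaussian's prediction there (floored at 0). Motion is
#' flagged as showing active processes when the tail excess exceeds a
#' threshold, by default 3x its bootstrap standard error. Purely thermal
#' motion gives sigma^2 = 2*D*lag and near-zero excess kurtosis;
#' motor-driven bursts fatten the tails beyond the Gaussian core.
#'
#' @param trajs list of [trajectory()] objects (or one), or `NULL` if
#'   `displacements` is given directly.
#' @param lag_s displacement lag, s (default 0.1).
#' @param bin_width_um histogram bin width, um (default 0.005).
#' @param gaussian_window_um central fit window, um (default +/- 0.03).
#' @param active_threshold `"3se"` (default) or a numeric absolute
#'   threshold on the tail excess.
#' @param n_boot bootstrap resamples for the tail-excess SE.
#' @param seed RNG seed for the bootstrap.
#' @param displacements optional pre-pooled per-axis displacements, um.
#' @return A `"VanHoveResult"` list: `bin_edges_um`, `bin_centers_um`,
#'   `probability`, `gaussian_fit` (`amplitude`, `sigma_um`),
#'   `tail_excess`, `tail_excess_se`, `excess_kurtosis`,
#'   `active_processes_detected`, `n_displacements`, `lag_s`.
#' @export
compute_van_hove <- function(trajs = NULL, lag_s = 0.1, bin_width_um = 0.005,
                             gaussian_window_um = c(-0.03, 0.03),
                             active_threshold = "3se", n_boot = 200,
                             seed = 1, displacements = NULL) {
  d <- displacements %||% .pooled_displacements(trajs, lag_s)$d
  if (length(d) < 2L) {
    stop("need at least one trajectory with >= 2 points at the lag",
         call. = FALSE)
  }
  hist <- .vh_histogram(d, bin_width_um)
  gfit <- .vh_gauss_fit(hist$centers, hist$prob, gaussian_window_um)
  excess <- .vh_tail_excess(hist$centers, hist$prob, gfit, gaussian_window_um)
  kurt <- mean((d - mean(d))^4) / stats::var(d)^2 - 3
  se <- local_seed(seed, {
    bs <- replicate(n_boot, {
      db <- d[sample.int(length(d), replace = TRUE)]
      hb <- .vh_histogram(db, bin_width_um)
      gb <- tryCatch(.vh_gauss_fit(hb$centers, hb$prob, gaussian_window_um),
                     error = function(e) NULL)
      if (is.null(gb)) NA_real_ else
        .vh_tail_excess(hb$centers, hb$prob, gb, gaussian_window_um)
    })
    stats::sd(bs, na.rm = TRUE)
  })
  threshold <- if (identical(active_threshold, "3se")) 3 * se else
    as.numeric(active_threshold)
  structure(list(bin_edges_um = hist$edges, bin_centers_um = hist$centers,
                 probability = hist$prob,
                 gaussian_fit = list(amplitude = gfit$amplitude,
                                     sigma_um = gfit$sigma_um,
                                     window_um = gaussian_window_um),
                 tail_excess = excess, tail_excess_se = se,
                 active_threshold = threshold,
                 excess_kurtosis = kurt,
                 active_processes_detected = excess > threshold,
                 n_displacements = length(d), lag_s = lag_s,
                 bin_width_um = bin_width_um),
            class = "VanHoveResult")
}

#' @export
print.VanHoveResult <- function(x, ...) {
  cat(sprintf(
    "<VanHove: n = %d displacements at lag %.3g s; sigma = %.4g um; tail excess = %.3g (SE %.2g); kurtosis excess = %.3g; active = %s>\n",
    x$n_displacements, x$lag_s, x$gaussian_fit$sigma_um, x$tail_excess,
    x$tail_excess_se, x$excess_kurtosis, x$active_processes_detected))
  invisible(x)
}

#' Partition displacements by proximity to nuclei
#'
#' Each per-axis displacement is assigned to the `near` or `far` group by
#' the distance of its starting point to the nearest nucleus border
#' (threshold: the median distance over all displacement start points,
#' unless given). Both groups get a Van Hove analysis, plus a two-sample
#' comparison of displacement magnitudes: a Wilcoxon rank-sum test on
#' |displacement| and the near/far displacement variance ratio. A group
#' with fewer than 50 displacements marks the comparison as underpowered.
#'
#' @param trajs list of [trajectory()] objects.
#' @param map a `"NucleusMap"`.
#' @param threshold_um proximity threshold, um; `NULL` = median distance.
#' @param lag_s displacement lag, s.
#' @param ... further arguments to [compute_van_hove()].
#' @return A list: `near`, `far` (each: `displacements_um`,
#'   `proximity_um`, `van_hove` or NULL, `n`), `threshold_um`,
#'   `comparison` (`wilcox_p`, `wilcox_statistic`, `variance_ratio`,
#'   `near_sigma_um`, `far_sigma_um`, `underpowered`).
#' @export
partition_by_proximity <- function(trajs, map, threshold_um = NULL,
                                   lag_s = 0.1, ...) {
  if (!is.null(threshold_um) && threshold_um <= 0) {
    stop("`threshold_um` must be positive", call. = FALSE)
  }
  pooled <- .pooled_displacements(trajs, lag_s)
  if (length(pooled$d) == 0L) stop("no displacements at this lag",
                                   call. = FALSE)
  prox <- distance_to_nuclei(cbind(pooled$x0, pooled$y0), map)
  threshold_um <- threshold_um %||% stats::median(prox)
  near <- prox <= threshold_um
  make_group <- function(sel, label) {
    d <- pooled$d[sel]
    vh <- if (length(d) >= 50L) {
      tryCatch(compute_van_hove(displacements = d, lag_s = lag_s, ...),
               error = function(e) NULL)
    } else NULL
    list(displacements_um = d, proximity_um = prox[sel], group = label,
         van_hove = vh, n = length(d))
  }
  g_near <- make_group(near, "near")
  g_far <- make_group(!near, "far")
  underpowered <- g_near$n < 50L || g_far$n < 50L
  comparison <- if (g_near$n >= 1L && g_far$n >= 1L) {
    wt <- stats::wilcox.test(abs(g_near$displacements_um),
                             abs(g_far$displacements_um))
    list(wilcox_p = wt$p.value, wilcox_statistic = unname(wt$statistic),
         variance_ratio = stats::var(g_near$displacements_um) /
           stats::var(g_far$displacements_um),
         near_sigma_um = if (!is.null(g_near$van_hove))
           g_near$van_hove$gaussian_fit$sigma_um else NA_real_,
         far_sigma_um = if (!is.null(g_far$van_hove))
           g_far$van_hove$gaussian_fit$sigma_um else NA_real_,
         underpowered = underpowered)
  } else {
    list(wilcox_p = NA_real_, wilcox_statistic = NA_real_,
         variance_ratio = NA_real_, near_sigma_um = NA_real_,
         far_sigma_um = NA_real_, underpowered = TRUE)
  }
  list(near = g_near, far = g_far, threshold_um = threshold_um,
       comparison = comparison)
}
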