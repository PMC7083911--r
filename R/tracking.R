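## Spot detection and trajectory linking for diffraction-limited movies.
## Detection: band-pass filter (Gaussian smoothing minus boxcar background),
## local maxima above a percentile threshold, iterative centroid refinement
## in the blob window; mass = background-subtracted integrated intensity.
## Linking: greedy global nearest neighbour per frame pair with gap closing.

## replicate-padded separable convolution with a 1-D kernel along both axes
.sep_convolve <- function(img, kernel) {
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(h), rep(h, r)),
             c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  tmp <- matrix(0, h + 2L * r, w)
  for (j in seq_len(k)) {
    tmp <- tmp + kernel[j] * pad[, j:(j + w - 1L), drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (i in seq_len(k)) {
    out <- out + kernel[i] * tmp[i:(i + h - 1L), , drop = FALSE]
  }
  out
}

## max over a (2r+1)-square neighbourhood (separable dilation)
.local_max_filter <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (s in seq_len(r)) {
    shifted_u <- rbind(out[-seq_len(1L), , drop = FALSE], out[h, , drop = FALSE])
    shifted_d <- rbind(out[1L, , drop = FALSE], out[-h, , drop = FALSE])
    out <- pmax(out, shifted_u, shifted_d)
  }
  tmp <- out
  for (s in seq_len(r)) {
    shifted_l <- cbind(tmp[, -1L, drop = FALSE], tmp[, w, drop = FALSE])
    shifted_r <- cbind(tmp[, 1L, drop = FALSE], tmp[, -w, drop = FALSE])
    tmp <- pmax(tmp, shifted_l, shifted_r)
  }
  tmp
}

.bandpass <- function(img, blob_diameter_px, noise_sigma_px = 1) {
  r <- (blob_diameter_px - 1L) %/% 2L
  xs <- -ceiling(3 * noise_sigma_px):ceiling(3 * noise_sigma_px)
  g <- exp(-xs^2 / (2 * noise_sigma_px^2)); g <- g / sum(g)
  smooth <- .sep_convolve(img, g)
  box <- rep(1 / blob_diameter_px, blob_diameter_px)
  background <- .sep_convolve(img, box)
  pmax(smooth - background, 0)
}

#' Detect diffraction-limited spots in one frame
#'
#' Band-pass filters the image (Gaussian noise smoothing minus a boxcar
#' background estimate over the blob diameter), finds local maxima above a
#' percentile threshold, and refines each candidate to sub-pixel precision
#' by iterated intensity centroiding within the blob window. Mass is the
#' background-subtracted intensity sum over the circular blob mask.
#'
#' @param frame 2-D numeric matrix of nonnegative intensities.
#' @param blob_diameter_px odd blob diameter in pixels (default 11).
#' @param min_mass minimum integrated mass to keep a spot (default 0).
#' @param percentile_threshold local maxima must exceed this percentile of
#'   the band-passed image (default 64).
#' @return Data frame of class `"SpotTable"` with columns `x_px`, `y_px`
#'   (0-based sub-pixel positions), `mass`, `size_px`.
#' @export
detect_spots <- function(frame, blob_diameter_px = 11, min_mass = 0,
                         percentile_threshold = 64) {
  if (!is.matrix(frame) || any(frame < 0)) {
    stop("`frame` must be a nonnegative 2-D matrix", call. = FALSE)
  }
  blob_diameter_px <- as.integer(blob_diameter_px)
  if (blob_diameter_px %% 2L == 0L) {
    stop("`blob_diameter_px` must be odd", call. = FALSE)
  }
  r <- (blob_diameter_px - 1L) %/% 2L
  bp <- .bandpass(frame, blob_diameter_px)
  thr <- stats::quantile(bp, percentile_threshold / 100, names = FALSE)
  is_max <- bp == .local_max_filter(bp, r) & bp > thr & bp > 0
  ## peaks too close to the border cannot be refined
  h <- nrow(bp); w <- ncol(bp)
  is_max[c(seq_len(r), h - seq_len(r) + 1L), ] <- FALSE
  is_max[, c(seq_len(r), w - seq_len(r) + 1L)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(structure(data.frame(x_px = numeric(), y_px = numeric(),
                                mass = numeric(), size_px = numeric()),
                     class = c("SpotTable", "data.frame")))
  }
  off <- expand.grid(dy = -r:r, dx = -r:r)
  mask <- sqrt(off$dx^2 + off$dy^2) <= r
  off <- off[mask, ]
  ## global background estimate for the mass: a spot occupies a small
  ## fraction of the frame, so the median is the background level
  bg <- stats::median(frame)
  spots <- lapply(seq_len(nrow(idx)), function(i) {
    cy <- idx[i, 1L]; cx <- idx[i, 2L]
    gx <- gy <- 0
    for (iter in 1:10) {
      iy <- cy + off$dy; ix <- cx + off$dx
      keep <- iy >= 1L & iy <= h & ix >= 1L & ix <= w
      v <- bp[cbind(iy[keep], ix[keep])]
      m <- sum(v)
      if (m <= 0) return(NULL)
      gx <- sum(v * off$dx[keep]) / m
      gy <- sum(v * off$dy[keep]) / m
      if ((abs(gx) <= 0.5 && abs(gy) <= 0.5) || iter == 10L) {
        vr <- pmax(frame[cbind(iy[keep], ix[keep])] - bg, 0)
        mr <- sum(vr)
        rg <- if (mr > 0)
          sqrt(sum(vr * (off$dx[keep]^2 + off$dy[keep]^2)) / mr) else NA_real_
        return(data.frame(x_px = cx - 1 + gx, y_px = cy - 1 + gy,
                          mass = mr, size_px = rg))
      }
      cx <- cx + sign(gx) * (abs(gx) > 0.5)
      cy <- cy + sign(gy) * (abs(gy) > 0.5)
      cx <- min(max(cx, r + 1L), w - r)
      cy <- min(max(cy, r + 1L), h - r)
    }
  })
  out <- do.call(rbind, spots)
  if (is.null(out)) {
    out <- data.frame(x_px = numeric(), y_px = numeric(),
                      mass = numeric(), size_px = numeric())
  }
  ## merge duplicates refined to the same position
  out <- out[!duplicated(round(cbind(out$x_px, out$y_px), 2)), , drop = FALSE]
  out <- out[out$mass >= min_mass, , drop = FALSE]
  out <- out[order(out$x_px, out$y_px), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("SpotTable", "data.frame"))
}

#' Linking parameters
#'
#' Defaults follow typical nanosheet-tracking settings: blob diameter 11 px,
#' search range 9 px between consecutive frames, gap memory 300 frames, and
#' a minimum trajectory length of 300 points (glycerol movies; 200 is used
#' for embryo recordings).
#'
#' @param search_range_px maximum displacement between consecutive frames, px.
#' @param memory_frames maximum gap over which a vanished particle keeps
#'   its identity, frames.
#' @param min_length minimum number of points for a trajectory to be kept.
#' @param blob_diameter_px odd detection blob diameter, px.
#' @return A `"LinkParams"` list.
#' @export
link_params <- function(search_range_px = 9, memory_frames = 300,
                        min_length = 300, blob_diameter_px = 11) {
  .assert_scalar_pos(search_range_px, "search_range_px")
  if (as.integer(blob_diameter_px) %% 2L == 0L) {
    stop("`blob_diameter_px` must be odd", call. = FALSE)
  }
  structure(list(search_range_px = search_range_px,
                 memory_frames = as.integer(memory_frames),
                 min_length = as.integer(min_length),
                 blob_diameter_px = as.integer(blob_diameter_px)),
            class = "LinkParams")
}

#' Link per-frame spots into trajectories
#'
#' Frame-pair assignment is greedy global nearest neighbour: all candidate
#' (track, spot) pairs within `search_range_px` of the track's last known
#' position are sorted by squared displacement (ties broken by the spot's
#' (x, y) lexicographic order, then track id — deterministic) and accepted
#' greedily. Tracks unseen for more than `memory_frames` frames expire;
#' leftover spots start new tracks; trajectories shorter than `min_length`
#' points are discarded. Positions are converted to um and times to s.
#'
#' @param spots_by_frame list of spot tables (one per consecutive frame),
#'   as from [detect_spots()].
#' @param params a [link_params()] object.
#' @param pixel_size_um physical pixel size, um/px.
#' @param frame_interval_s frame interval, s.
#' @return List of [trajectory()] objects.
#' @export
link_spots <- function(spots_by_frame, params = link_params(),
                       pixel_size_um = 1, frame_interval_s = 1) {
  if (!inherits(params, "LinkParams")) stop("`params` must be link_params()")
  active <- list()   # each: list(id, x, y, last_frame, rows = data.frame)
  done <- list()
  next_id <- 1L
  sr2 <- params$search_range_px^2
  for (f in seq_along(spots_by_frame)) {
    sp <- spots_by_frame[[f]]
    sp <- sp[order(sp$x_px, sp$y_px), , drop = FALSE]
    ## expire tracks whose gap exceeded memory
    if (length(active) > 0L) {
      gaps <- vapply(active, function(a) f - a$last_frame - 1L, integer(1))
      expired <- gaps > params$memory_frames
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    ns <- nrow(sp)
    assigned_spot <- rep(FALSE, ns)
    if (length(active) > 0L && ns > 0L) {
      ax <- vapply(active, `[[`, numeric(1), "x")
      ay <- vapply(active, `[[`, numeric(1), "y")
      d2 <- outer(ax, sp$x_px, "-")^2 + outer(ay, sp$y_px, "-")^2
      cand <- which(d2 <= sr2, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(d2[cand], sp$x_px[cand[, 2L]], sp$y_px[cand[, 2L]],
                     vapply(active, `[[`, integer(1), "id")[cand[, 1L]])
        cand <- cand[ord, , drop = FALSE]
        used_track <- rep(FALSE, length(active))
        for (i in seq_len(nrow(cand))) {
          ti <- cand[i, 1L]; si <- cand[i, 2L]
          if (used_track[ti] || assigned_spot[si]) next
          used_track[ti] <- TRUE; assigned_spot[si] <- TRUE
          a <- active[[ti]]
          a$rows <- rbind(a$rows, data.frame(frame = f - 1L, x = sp$x_px[si],
                                             y = sp$y_px[si],
                                             mass = sp$mass[si]))
          a$x <- sp$x_px[si]; a$y <- sp$y_px[si]; a$last_frame <- f
          active[[ti]] <- a
        }
      }
    }
    if (ns > 0L && any(!assigned_spot)) {
      for (si in which(!assigned_spot)) {
        active[[length(active) + 1L]] <- list(
          id = next_id, x = sp$x_px[si], y = sp$y_px[si], last_frame = f,
          rows = data.frame(frame = f - 1L, x = sp$x_px[si], y = sp$y_px[si],
                            mass = sp$mass[si]))
        next_id <- next_id + 1L
      }
    }
  }
  done <- c(done, active)
  done <- done[order(vapply(done, `[[`, integer(1), "id"))]
  kept <- Filter(function(a) nrow(a$rows) >= params$min_length, done)
  lapply(kept, function(a) {
    trajectory(paste0("p", a$id),
               t_s = a$rows$frame * frame_interval_s,
               x_um = a$rows$x * pixel_size_um,
               y_um = a$rows$y * pixel_size_um,
               mass = a$rows$mass, frame = a$rows$frame,
               pixel_size_um = pixel_size_um)
  })
}

#' Sum-bin a movie 2x2
#'
#' Optional pre-processing for large recordings: each output pixel is the
#' sum of a 2x2 input block (odd trailing rows/columns are dropped), and
#' the effective pixel size doubles.
#'
#' @param movie a `"SyntheticMovie"` or a h x w x n array.
#' @return Same type with halved spatial dimensions.
#' @export
bin2x2 <- function(movie) {
  frames <- if (inherits(movie, "SyntheticMovie")) movie$frames else movie
  h <- 2L * (dim(frames)[1L] %/% 2L); w <- 2L * (dim(frames)[2L] %/% 2L)
  nf <- dim(frames)[3L]
  out <- frames[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
         frames[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
         frames[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE] +
         frames[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]
  if (inherits(movie, "SyntheticMovie")) {
    movie$frames <- out
    movie$pixel_size_um <- movie$pixel_size_um * 2
    movie
  } else out
}

#' Detect and link spots across a whole movie
#'
#' Convenience wrapper: runs [detect_spots()] on every frame and
#' [link_spots()] on the result, using the movie's own pixel size and
#' frame interval when available.
#'
#' @param movie a `"SyntheticMovie"` or h x w x n array.
#' @param params a [link_params()].
#' @param pixel_size_um,frame_interval_s used when `movie` is a bare array.
#' @param min_mass,percentile_threshold passed to [detect_spots()].
#' @return List of [trajectory()] objects.
#' @export
track_movie <- function(movie, params = link_params(), pixel_size_um = NULL,
                        frame_interval_s = NULL, min_mass = 0,
                        percentile_threshold = 64) {
  if (inherits(movie, "SyntheticMovie")) {
    frames <- movie$frames
    pixel_size_um <- pixel_size_um %||% movie$pixel_size_um
    frame_interval_s <- frame_interval_s %||% movie$frame_interval_s
  } else frames <- movie
  spots <- lapply(seq_len(dim(frames)[3L]), function(f) {
    detect_spots(frames[, , f], params$blob_diameter_px, min_mass,
                 percentile_threshold)
  })
  link_spots(spots, params, pixel_size_um, frame_interval_s)
}
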