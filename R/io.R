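## Shared readers/writers. All writes are atomic (write-then-rename).

#' Write a movie as 16-bit multi-page TIFF with a JSON sidecar
#'
#' Intensities are scaled into the 16-bit range by `scale` (default: the
#' maximum intensity maps to 65535) and the scale is recorded in the
#' sidecar (`<path>.json`) together with `pixel_size_um`,
#' `frame_interval_s` and the generator seed, so the movie round-trips.
#'
#' @param movie a `"SyntheticMovie"` or h x w x n array.
#' @param path output TIFF path.
#' @param pixel_size_um,frame_interval_s,seed metadata (taken from the
#'   movie object when available).
#' @param scale counts per intensity unit; `NULL` = auto.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, pixel_size_um = NULL,
                             frame_interval_s = NULL, seed = NULL,
                             scale = NULL) {
  if (inherits(movie, "SyntheticMovie")) {
    frames <- movie$frames
    pixel_size_um <- pixel_size_um %||% movie$pixel_size_um
    frame_interval_s <- frame_interval_s %||% movie$frame_interval_s
    seed <- seed %||% movie$seed
  } else frames <- movie
  mx <- max(frames)
  scale <- scale %||% if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(frames)[3L]), function(f) {
    m <- round(frames[, , f] * scale)
    m[m > 65535] <- 65535; m[m < 0] <- 0
    m / 65535  # the tiff package expects [0,1]
  })
  .atomic_write(function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 16L, compression = "none")
  }, path)
  sidecar <- list(pixel_size_um = pixel_size_um,
                  frame_interval_s = frame_interval_s,
                  seed = seed, intensity_scale = scale,
                  schema = "ebnstrack movie sidecar v1")
  .atomic_write(function(tmp) {
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA)
  }, paste0(path, ".json"))
  invisible(path)
}

#' Read a multi-page TIFF movie (+ optional JSON sidecar)
#'
#' @param path TIFF file; if `<path>.json` exists its metadata and
#'   intensity scale are applied (returning the original intensity units).
#' @return A list: `frames` (h x w x n array), `pixel_size_um`,
#'   `frame_interval_s`, `seed`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]),
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]]
  meta <- list(pixel_size_um = NA_real_, frame_interval_s = NA_real_,
               seed = NULL, intensity_scale = 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta[names(jsonlite::read_json(sidecar, simplifyVector = TRUE))] <-
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  list(frames = frames / meta$intensity_scale,
       pixel_size_um = meta$pixel_size_um,
       frame_interval_s = meta$frame_interval_s, seed = meta$seed)
}

#' Write a nucleus map as a vertex-list CSV
#'
#' Columns `nucleus_id, vertex, x_um, y_um`, one row per polygon vertex.
#'
#' @param map a `"NucleusMap"`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_nucleus_map_csv <- function(map, path) {
  tab <- do.call(rbind, lapply(seq_along(map$polygons), function(i) {
    ring <- map$polygons[[i]]
    data.frame(nucleus_id = i, vertex = seq_len(nrow(ring)),
               x_um = ring[, 1L], y_um = ring[, 2L])
  }))
  .atomic_write(function(tmp) {
    utils::write.csv(tab, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read a nucleus map from a vertex-list CSV
#'
#' @param path CSV with columns `nucleus_id, x_um, y_um` (vertex order =
#'   row order within each nucleus).
#' @return A `"NucleusMap"`.
#' @export
read_nucleus_map_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("nucleus_id", "x_um", "y_um")
  if (!all(need %in% names(tab))) {
    stop("nucleus map CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  polys <- lapply(split(tab, tab$nucleus_id), function(d) {
    if (nrow(d) < 3L) stop("nucleus ring with < 3 vertices", call. = FALSE)
    cbind(x_um = d$x_um, y_um = d$y_um)
  })
  centers <- t(vapply(polys, colMeans, numeric(2)))
  structure(list(polygons = unname(polys),
                 centers = unname(centers), radius_um = NA_real_,
                 seed = NULL),
            class = "NucleusMap")
}

#' Write a saturation sweep as CSV
#'
#' Columns `power_uW, counts_per_s, direction`.
#' @param curve a `"SaturationCurve"`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_saturation_csv <- function(curve, path) {
  tab <- data.frame(power_uW = curve$P_exc_uW,
                    counts_per_s = curve$detected_counts_per_s,
                    direction = curve$direction %||% "up")
  .atomic_write(function(tmp) {
    utils::write.csv(tab, tmp, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read a saturation sweep from CSV
#'
#' @param path CSV with columns `power_uW, counts_per_s` (optional
#'   `direction`).
#' @return A `"SaturationCurve"` data frame.
#' @export
read_saturation_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("power_uW", "counts_per_s") %in% names(tab))) {
    stop("saturation CSV must have columns power_uW, counts_per_s",
         call. = FALSE)
  }
  out <- data.frame(P_exc_uW = tab$power_uW,
                    detected_counts_per_s = tab$counts_per_s,
                    direction = if ("direction" %in% names(tab))
                      tab$direction else "up")
  class(out) <- c("SaturationCurve", "data.frame")
  out
}
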