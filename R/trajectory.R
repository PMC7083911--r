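#' Construct a single-particle trajectory
#'
#' The canonical trajectory container shared by all analysis stages:
#' time-ordered 2-D positions in micrometres with an optional per-frame
#' integrated brightness ("mass"). All lengths are in um and times in s;
#' pixel units appear only at I/O boundaries.
#'
#' @param particle_id identifier (scalar).
#' @param t_s strictly increasing times, s.
#' @param x_um,y_um positions, um, same length as `t_s`.
#' @param mass per-frame background-subtracted integrated brightness
#'   (arbitrary units), or `NA`.
#' @param frame optional integer frame indices.
#' @param pixel_size_um the pixel size used for any px-to-um conversion,
#'   or `NA` when positions were generated directly in um.
#' @return An object of class `"Trajectory"`: a data frame with columns
#'   `particle_id`, `frame`, `t_s`, `x_um`, `y_um`, `mass`.
#' @export
trajectory <- function(particle_id, t_s, x_um, y_um, mass = NA_real_,
                       frame = NULL, pixel_size_um = NA_real_) {
  n <- length(t_s)
  if (n < 1L) stop("trajectory must have at least one point", call. = FALSE)
  if (length(x_um) != n || length(y_um) != n) {
    stop("x_um, y_um and t_s must have equal length", call. = FALSE)
  }
  if (n > 1L && any(diff(t_s) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  mass <- rep_len(as.numeric(mass), n)
  frame <- if (is.null(frame)) seq_len(n) - 1L else as.integer(frame)
  out <- data.frame(
    particle_id = rep_len(particle_id, n), frame = frame,
    t_s = as.numeric(t_s), x_um = as.numeric(x_um), y_um = as.numeric(y_um),
    mass = mass
  )
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("Trajectory", "data.frame")
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory %s: %d points, %.3g s at dt = %.4g s>\n",
              x$particle_id[1L], nrow(x),
              x$t_s[nrow(x)] - x$t_s[1L],
              if (nrow(x) > 1L) x$t_s[2L] - x$t_s[1L] else NA_real_))
  invisible(x)
}

#' Maximum integrated brightness along a trajectory
#'
#' The maximum of the per-frame mass is used as a particle's fluorescence
#' intensity, which is robust to transient out-of-focus excursions and
#' rotations of a non-spherical emitter.
#'
#' @param traj a [trajectory()].
#' @return Scalar maximum mass.
#' @export
trajectory_max_mass <- function(traj) {
  if (!inherits(traj, "Trajectory")) stop("`traj` must be a Trajectory")
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  m <- traj$mass[is.finite(traj$mass)]
  if (length(m) == 0L) stop("trajectory carries no finite mass values",
                            call. = FALSE)
  max(m)
}

.traj_schema <- c("particle_id", "frame", "t_s", "x_um", "y_um", "mass")
.traj_header <- "# ebnstrack trajectory schema v1"

#' Write trajectories to CSV
#'
#' One row per (particle, frame); columns `particle_id, frame, t_s, x_um,
#' y_um, mass` with a versioned header comment. The write is atomic
#' (write-then-rename).
#'
#' @param trajs a list of [trajectory()] objects (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajs, path) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  tab <- do.call(rbind, lapply(trajs, function(tr) as.data.frame(tr)[.traj_schema]))
  .atomic_write(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(.traj_header, con)
    utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read trajectories from CSV
#'
#' @param path CSV file written by [write_trajectories_csv()] (or any file
#'   with the same mandatory header columns).
#' @param pixel_size_um recorded on each trajectory for provenance.
#' @return A list of [trajectory()] objects, one per `particle_id`.
#' @export
read_trajectories_csv <- function(path, pixel_size_um = NA_real_) {
  tab <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(.traj_schema, names(tab))
  if (length(missing) > 0L) {
    stop("trajectory CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(split(tab, tab$particle_id), function(d) {
    d <- d[order(d$t_s), ]
    trajectory(d$particle_id[1L], d$t_s, d$x_um, d$y_um, d$mass,
               frame = d$frame, pixel_size_um = pixel_size_um)
  })
}
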