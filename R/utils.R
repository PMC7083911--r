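#' @keywords internal
"_PACKAGE"

## Boltzmann constant, J/K (2019 SI exact value)
.kB <- 1.380649e-23

#' Evaluate code under a local RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded generators do not perturb the global random stream.
#' A `NULL` seed leaves the RNG untouched.
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.assert_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("`%s` must be a single finite %s number", name,
                 if (strict) "positive" else "nonnegative"), call. = FALSE)
  }
  invisible(x)
}

## Uniform-sampling check: returns the common frame interval or signals.
.frame_interval <- function(t_s, tol = 1e-9) {
  if (length(t_s) < 2L) stop("need at least 2 time points", call. = FALSE)
  dt <- diff(t_s)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > tol * max(dt)) {
    stop("trajectory is not uniformly sampled; resample before analysis",
         call. = FALSE)
  }
  mean(dt)
}

## Atomic file write: materialise to a temp file in the same directory,
## then rename over the target (write-then-rename contract).
.atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
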