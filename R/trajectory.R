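#' Trajectories
#'
#' A trajectory couples a topology (molecule tibble) with an ordered list of
#' coordinate frames (each an n_atoms x 3 matrix, Angstrom) and strictly
#' increasing frame times in ps.
#'
#' @param topology A molecule tibble describing the atoms.
#' @param frames List of n_atoms x 3 numeric matrices.
#' @param times Numeric vector of frame times in ps, strictly increasing.
#' @return An object of class `flavotune_trajectory`.
#' @export
trajectory <- function(topology, frames, times = seq_along(frames)) {
  topology <- as_molecule(topology)
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(topology)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    dimnames(f) <- NULL
    if (nrow(f) != n || ncol(f) != 3) {
      stop("Every frame must be an n_atoms x 3 matrix (expected ", n,
           " atoms)", call. = FALSE)
    }
    f
  })
  times <- as.numeric(times)
  if (length(times) != length(frames)) {
    stop("times must have one entry per frame", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("Frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "flavotune_trajectory")
}

#' @rdname trajectory
#' @param x Object to test.
#' @export
is_trajectory <- function(x) inherits(x, "flavotune_trajectory")

#' @export
print.flavotune_trajectory <- function(x, ...) {
  cat("<flavotune_trajectory> ", length(x$frames), " frames x ",
      nrow(x$topology), " atoms, t = ", x$times[1], " .. ",
      x$times[length(x$times)], " ps\n", sep = "")
  invisible(x)
}

#' @export
length.flavotune_trajectory <- function(x) length(x$frames)

#' Tidy a trajectory into a long tibble
#'
#' One row per atom per frame with columns `frame`, `time`, the topology
#' identity columns and the frame coordinates.
#'
#' @param x A trajectory.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.flavotune_trajectory <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$frames), x$frames, function(k, f) {
    out <- x$topology
    out$x <- f[, 1]; out$y <- f[, 2]; out$z <- f[, 3]
    dplyr::mutate(out, frame = k, time = x$times[k], .before = 1)
  })
}

#' Extract one frame as a molecule tibble
#'
#' @param traj A trajectory.
#' @param i Frame index.
#' @return The topology with coordinates replaced by frame `i`.
#' @export
frame_molecule <- function(traj, i) {
  stopifnot(is_trajectory(traj), i >= 1, i <= length(traj$frames))
  m <- traj$topology
  f <- traj$frames[[i]]
  m$x <- f[, 1]; m$y <- f[, 2]; m$z <- f[, 3]
  m
}
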