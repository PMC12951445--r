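# Averaged-configuration electrostatic environments (ASEC): many trajectory
# snapshots merged into a single point-charge cloud whose charges are scaled
# by 1/N, so its potential at any external point equals the frame-averaged
# potential.

#' Extract frames at fixed time intervals
#'
#' Picks `count` frames at times `interval, 2*interval, ..., count*interval`
#' ps, taking the nearest stored frame for each target (earlier frame on
#' ties), as when sampling snapshots from a production run.
#'
#' @param traj A trajectory.
#' @param interval Sampling interval in ps.
#' @param count Number of frames to extract.
#' @return Integer vector of frame indices (length `count`), with the target
#'   times as the `target_times` attribute.
#' @export
extract_frames <- function(traj, interval = 50, count = 100) {
  stopifnot(is_trajectory(traj), interval > 0, count >= 1)
  duration <- max(traj$times)
  if (duration < interval * count) {
    achievable <- floor(duration / interval)
    stop("Trajectory spans ", duration, " ps; ", count, " frames at ",
         interval, " ps intervals need ", interval * count,
         " ps (achievable count: ", achievable, ")", call. = FALSE)
  }
  targets <- interval * seq_len(count)
  idx <- vapply(targets, function(t0) {
    d <- abs(traj$times - t0)
    which(d == min(d))[1]
  }, integer(1))
  attr(idx, "target_times") <- targets
  idx
}

#' Merge frames into an ASEC environment
#'
#' Concatenates the selected frames' atoms into one point-charge cloud with
#' each charge scaled by 1/N (N = number of frames), so the merged cloud's
#' potential at any external point equals the mean of the per-frame
#' potentials. Optional Lennard-Jones columns (`lj_epsilon`, `lj_sigma`) are
#' carried with epsilon scaled by 1/N and sigma unchanged (see
#' `scale_lj`).
#'
#' @param traj A trajectory whose topology carries a `charge` column.
#' @param frame_idx Frame indices to merge (default: all frames).
#' @param scale_lj If `TRUE` (default) and the topology has `lj_epsilon`,
#'   scale it by 1/N; if `FALSE`, carry Lennard-Jones parameters unscaled.
#' @return An `asec_environment`: a charge-set tibble with extra columns
#'   `frame` and `serial`, and attributes `n_frames`, `scale`,
#'   `frame_times`.
#' @export
merge_asec <- function(traj, frame_idx = seq_along(traj$frames),
                       scale_lj = TRUE) {
  stopifnot(is_trajectory(traj), length(frame_idx) >= 1)
  topo <- traj$topology
  if (!"charge" %in% names(topo) || anyNA(topo$charge)) {
    stop("Trajectory topology needs per-atom charges to build an ASEC ",
         "environment", call. = FALSE)
  }
  n <- length(frame_idx)
  rows <- lapply(frame_idx, function(k) {
    f <- traj$frames[[k]]
    out <- tibble::tibble(
      x = f[, 1], y = f[, 2], z = f[, 3],
      charge = topo$charge / n,
      frame = k, serial = topo$serial
    )
    if ("lj_epsilon" %in% names(topo)) {
      out$lj_epsilon <- if (scale_lj) topo$lj_epsilon / n else topo$lj_epsilon
    }
    if ("lj_sigma" %in% names(topo)) out$lj_sigma <- topo$lj_sigma
    out
  })
  env <- dplyr::bind_rows(rows)
  attr(env, "n_frames") <- n
  attr(env, "scale") <- 1 / n
  attr(env, "frame_times") <- traj$times[frame_idx]
  class(env) <- c("asec_environment", class(tibble::tibble()))
  env
}

#' Zero and redistribute charges at a QM/MM boundary
#'
#' To avoid over-polarising a QM region capped by a link atom, the charges of
#' MM atoms near the link atom are set to zero and their total is split
#' equally among a recipient set. Total charge is conserved exactly.
#'
#' @param charges A tibble with a `charge` column (e.g. a molecule or
#'   charge set).
#' @param zeroed Integer row indices whose charges are zeroed.
#' @param recipients Integer row indices receiving the removed charge in
#'   equal shares; must be disjoint from `zeroed`.
#' @return `charges` with the adjusted `charge` column.
#' @export
redistribute_boundary <- function(charges, zeroed, recipients) {
  stopifnot("charge" %in% names(charges))
  n <- nrow(charges)
  if (length(zeroed) > 0 && (min(zeroed) < 1 || max(zeroed) > n)) {
    stop("zeroed indices out of range", call. = FALSE)
  }
  if (length(recipients) > 0 && (min(recipients) < 1 || max(recipients) > n)) {
    stop("recipient indices out of range", call. = FALSE)
  }
  if (length(intersect(zeroed, recipients)) > 0) {
    stop("zeroed and recipient sets must be disjoint", call. = FALSE)
  }
  if (length(zeroed) == 0) return(charges)
  removed <- sum(charges$charge[zeroed])
  if (length(recipients) == 0) {
    if (abs(removed) > 1e-12) {
      stop("Cannot zero a net charge of ", format(removed),
           " e with no recipient atoms", call. = FALSE)
    }
    charges$charge[zeroed] <- 0
    return(charges)
  }
  charges$charge[zeroed] <- 0
  charges$charge[recipients] <- charges$charge[recipients] +
    removed / length(recipients)
  charges
}

#' Excitation-energy convergence test
#'
#' An iterative averaged-environment protocol is converged when the last
#' `window` successive excitation energies lie within `tol` of one another
#' (max - min over the window).
#'
#' @param energies Numeric vector of per-iteration excitation energies, eV.
#' @param tol Convergence tolerance in eV.
#' @param window Number of trailing iterations that must agree (>= 2).
#' @return A list: `converged`, `spread` (eV), `window_values`, `reason`.
#' @export
check_convergence <- function(energies, tol = 0.02, window = 4) {
  stopifnot(tol > 0, window >= 2)
  energies <- as.numeric(energies)
  if (length(energies) < window) {
    return(list(converged = FALSE, spread = NA_real_,
                window_values = energies,
                reason = paste0("only ", length(energies),
                                " iterations; need ", window)))
  }
  tail_vals <- utils::tail(energies, window)
  spread <- max(tail_vals) - min(tail_vals)
  list(converged = spread <= tol, spread = spread,
       window_values = tail_vals,
       reason = if (spread <= tol) "window spread within tolerance"
                else paste0("window spread ", format(spread), " eV > ",
                            format(tol), " eV"))
}

#' Run an iterative environment-refinement loop
#'
#' Drives the alternation between environment construction and excitation-
#' energy evaluation with a pluggable energy callback (the quantum-chemistry
#' step is external to this package). Iterates until [check_convergence()]
#' passes or `max_iter` is reached.
#'
#' @param energy_fn Function of the iteration index returning an excitation
#'   energy in eV.
#' @param max_iter Maximum iterations.
#' @param tol,window Passed to [check_convergence()].
#' @return A list: `energies`, `converged`, `n_iter`, `convergence` (the
#'   final [check_convergence()] result).
#' @export
run_asec_loop <- function(energy_fn, max_iter = 20, tol = 0.02, window = 4) {
  energies <- numeric(0)
  conv <- check_convergence(numeric(0) + NA_real_, tol, window)
  for (it in seq_len(max_iter)) {
    energies <- c(energies, energy_fn(it))
    conv <- check_convergence(energies, tol, window)
    if (conv$converged) break
  }
  list(energies = energies, converged = conv$converged,
       n_iter = length(energies), convergence = conv)
}

#' Write an ASEC environment as a point-charge table
#'
#' Plain whitespace-delimited `x y z q` text, the lingua franca for feeding
#' point-charge environments to quantum-chemistry programs.
#'
#' @param env An `asec_environment` (or any charge-set tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_point_charges <- function(env, path) {
  writeLines(sprintf("%16.10f %16.10f %16.10f %14.10f",
                     env$x, env$y, env$z, env$charge), path)
  invisible(path)
}
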