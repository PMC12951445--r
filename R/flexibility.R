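# Per-residue flexibility analysis: superposition, RMSF, normalisation,
# above-average selection, chromophore proximity, and B-factor annotation.

# Kabsch least-squares superposition of moving (n x 3) onto fixed (n x 3);
# returns the transformed full-coordinate matrix when `apply_to` is given.
kabsch <- function(moving, fixed, apply_to = moving) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm)
  b <- sweep(fixed, 2, cf)
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(apply_to, 2, cm) %*% t(rot), 2, cf, "+")
}

# Indices of the alpha-carbon selection (one per residue where present).
ca_indices <- function(mol) {
  which(trimws(mol$name) == "CA" & toupper(mol$element) != "CA")
}

#' Superpose trajectory frames onto their mean structure
#'
#' Least-squares rigid-body (Kabsch) superposition of every frame onto an
#' iterated mean structure: frames are first aligned to frame 1, the aligned
#' mean is formed, and alignment onto the mean is refined (two passes). The
#' fit uses the alpha-carbon selection by default; the transform is applied
#' to all atoms.
#'
#' @param traj A trajectory with at least 2 frames.
#' @param selection Integer atom indices used for the fit; defaults to the
#'   CA atoms (all atoms when no CA present).
#' @param passes Mean-refinement passes.
#' @return The superposed trajectory.
#' @export
superpose_to_mean <- function(traj, selection = NULL, passes = 2) {
  stopifnot(is_trajectory(traj), length(traj$frames) >= 2)
  if (is.null(selection)) {
    selection <- ca_indices(traj$topology)
    if (length(selection) == 0) selection <- seq_len(nrow(traj$topology))
  }
  if (length(selection) < 3) {
    stop("Need at least 3 atoms in the fit selection", call. = FALSE)
  }
  sel_rank <- function(m) qr(sweep(m, 2, colMeans(m)))$rank
  if (sel_rank(traj$frames[[1]][selection, , drop = FALSE]) < 2) {
    stop("Fit selection is degenerate (collinear atoms)", call. = FALSE)
  }
  frames <- traj$frames
  ref <- frames[[1]][selection, , drop = FALSE]
  for (pass in seq_len(passes)) {
    frames <- lapply(frames, function(f) {
      kabsch(f[selection, , drop = FALSE], ref, apply_to = f)
    })
    ref <- Reduce(`+`, lapply(frames, function(f) {
      f[selection, , drop = FALSE]
    })) / length(frames)
  }
  trajectory(traj$topology, frames, traj$times)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue's alpha carbon about its
#' time-mean position, over an (already superposed) trajectory:
#' rmsf_r = sqrt(mean_t |x_rt - mean_t(x_rt)|^2). Residues without a CA atom
#' are excluded and reported in the `excluded_residues` attribute.
#'
#' @param traj A superposed trajectory (see [superpose_to_mean()]).
#' @param selection Optional integer atom indices (one atom per residue);
#'   defaults to the CA atoms.
#' @return An `rmsf_profile` tibble with columns `residue_id`, `rmsf`
#'   (Angstrom) and attribute `mean_rmsf`.
#' @export
rmsf <- function(traj, selection = NULL) {
  stopifnot(is_trajectory(traj))
  topo <- traj$topology
  if (is.null(selection)) {
    selection <- ca_indices(topo)
    all_res <- unique(topo$residue_id)
    excluded <- setdiff(all_res, topo$residue_id[selection])
    if (length(excluded) > 0) {
      message("Residue(s) without CA excluded from RMSF: ",
              paste(excluded, collapse = ", "))
    }
  } else {
    excluded <- integer(0)
  }
  if (length(selection) == 0) stop("Empty RMSF selection", call. = FALSE)
  nf <- length(traj$frames)
  coords <- array(unlist(lapply(traj$frames, function(f) {
    f[selection, , drop = FALSE]
  })), dim = c(length(selection), 3, nf))
  mean_pos <- apply(coords, c(1, 2), mean)
  dev2 <- sweep(coords, c(1, 2), mean_pos)^2
  msf <- apply(dev2, 1, sum) / nf   # sum over xyz and frames, / n_frames
  prof <- tibble::tibble(
    residue_id = topo$residue_id[selection],
    rmsf = sqrt(msf)
  )
  attr(prof, "mean_rmsf") <- mean(prof$rmsf)
  attr(prof, "excluded_residues") <- excluded
  class(prof) <- c("rmsf_profile", class(tibble::tibble()))
  prof
}

#' Normalise an RMSF profile to [0, 1]
#'
#' Affine map (x - min) / (max - min), so the stiffest residue sits at 0 and
#' the most flexible at 1. A constant profile maps to all zeros and is
#' flagged via the `degenerate` attribute.
#'
#' @param profile An `rmsf_profile` (or tibble with `rmsf`).
#' @return The profile with a `normalized` column.
#' @export
normalize_rmsf <- function(profile) {
  stopifnot(nrow(profile) > 0)
  r <- profile$rmsf
  span <- max(r) - min(r)
  degenerate <- span == 0
  profile$normalized <- if (degenerate) rep(0, length(r)) else (r - min(r)) / span
  attr(profile, "degenerate") <- degenerate
  profile
}

#' Select residues with above-average normalised flexibility
#'
#' Residues whose normalised RMSF is strictly greater than the mean
#' normalised RMSF (the set conventionally rendered as spheres).
#'
#' @param profile A normalised profile from [normalize_rmsf()].
#' @return Integer vector of residue ids.
#' @export
select_above_average <- function(profile) {
  if (!"normalized" %in% names(profile)) profile <- normalize_rmsf(profile)
  profile$residue_id[profile$normalized > mean(profile$normalized)]
}

#' Residues within a cutoff of a chromophore
#'
#' A residue is included iff any of its heavy atoms lies within `cutoff`
#' (inclusive) of any chromophore heavy atom; both structures must share one
#' coordinate frame. Around flavin cofactors the conventional cutoff is
#' 4 Angstrom.
#'
#' @param protein Protein molecule tibble.
#' @param chromophore Chromophore molecule tibble.
#' @param cutoff Distance cutoff in Angstrom.
#' @return A tibble with `residue_id`, `residue_name`, `chain`, `min_dist`;
#'   the row count is the proximity count.
#' @export
residues_within <- function(protein, chromophore, cutoff = 4.0) {
  ph <- heavy_atoms(protein)
  ch <- heavy_atoms(chromophore)
  if (nrow(ch) == 0) stop("Chromophore has no heavy atoms", call. = FALSE)
  if (nrow(ph) == 0) {
    return(tibble::tibble(residue_id = integer(0), residue_name = character(0),
                          chain = character(0), min_dist = numeric(0)))
  }
  pc <- coords_matrix(ph)
  cc <- coords_matrix(ch)
  # all-pairs min distance per protein atom
  d2min <- rep(Inf, nrow(pc))
  for (j in seq_len(nrow(cc))) {
    d2 <- (pc[, 1] - cc[j, 1])^2 + (pc[, 2] - cc[j, 2])^2 +
      (pc[, 3] - cc[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  ph$min_dist <- sqrt(d2min)
  out <- ph |>
    dplyr::group_by(.data$chain, .data$residue_id, .data$residue_name) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= cutoff) |>
    dplyr::arrange(.data$chain, .data$residue_id) |>
    dplyr::select("residue_id", "residue_name", "chain", "min_dist")
  out
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Annotates every atom of each residue with that residue's profile value
#' (normalised RMSF by default) at 2 decimal places, the conventional route
#' for colouring structures by flexibility. Residues absent from the profile
#' get B = 0.00 with a warning.
#'
#' @param mol Molecule tibble.
#' @param profile Profile tibble with `residue_id` and a value column.
#' @param path Output PDB path.
#' @param value_column Which profile column to write (default `normalized`,
#'   falling back to `rmsf`).
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(mol, profile, path, value_column = NULL) {
  if (is.null(value_column)) {
    value_column <- if ("normalized" %in% names(profile)) "normalized" else "rmsf"
  }
  vals <- profile[[value_column]][match(mol$residue_id, profile$residue_id)]
  if (anyNA(vals)) {
    missing <- unique(mol$residue_id[is.na(vals)])
    warning("Residue(s) absent from profile written with B = 0.00: ",
            paste(missing, collapse = ", "), call. = FALSE)
    vals[is.na(vals)] <- 0
  }
  write_pdb(mol, path, bfactor = round(vals, 2))
}
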