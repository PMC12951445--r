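# Electrostatic spectral tuning maps (ESTMs) and the first-order
# environment-shift estimators that connect projection maps to the
# singlet-triplet gap.
#
# Sign convention (the most error-prone contract in the package): a POSITIVE
# shift is a BLUE-shift (the excited state is destabilised relative to the
# ground state); a NEGATIVE shift is a RED-shift. A positive probe charge in
# a region where the state's difference density is negative red-shifts that
# state.

#' State difference charges
#'
#' Per-atom difference between excited-state and ground-state partial
#' charges (e) for one named electronic state, the first-order kernel of
#' spectral tuning. Excitation conserves total charge, so the entries must
#' sum to zero (tolerance 1e-6).
#'
#' @param state State name, e.g. `"S1_pipi"` or `"Tn_npi"`.
#' @param delta_q Numeric vector, one value per chromophore atom, e.
#' @return A `state_delta_charges` object.
#' @export
state_delta_charges <- function(state, delta_q) {
  delta_q <- as.numeric(delta_q)
  if (!all(is.finite(delta_q))) stop("delta_q has non-finite values",
                                     call. = FALSE)
  if (abs(sum(delta_q)) > 1e-6) {
    stop("delta_q must sum to zero (charge-conserving excitation); got ",
         format(sum(delta_q)), call. = FALSE)
  }
  structure(list(state = state, delta_q = delta_q),
            class = "state_delta_charges")
}

#' @export
print.state_delta_charges <- function(x, ...) {
  cat("<state_delta_charges> state ", x$state, ", ", length(x$delta_q),
      " atoms, range [", format(min(x$delta_q)), ", ",
      format(max(x$delta_q)), "] e\n", sep = "")
  invisible(x)
}

#' Read state difference charges from two-column text
#'
#' Whitespace-delimited lines `atom_serial delta_q`; serials must match the
#' molecule's atom serials (order is resolved by serial).
#'
#' @param path Input path.
#' @param mol Molecule whose atom order defines the vector layout.
#' @param state State name to attach.
#' @return A [state_delta_charges()] object.
#' @export
read_delta_charges <- function(path, mol, state = "state") {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("serial", "delta_q"))
  idx <- match(mol$serial, df$serial)
  if (anyNA(idx)) {
    stop("Delta-charge file is missing serial(s): ",
         paste(mol$serial[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  state_delta_charges(state, df$delta_q[idx])
}

#' Compute an electrostatic spectral tuning map
#'
#' First-order (frozen-density) model of the excitation-energy shift a probe
#' charge induces at each point of a scaled van der Waals surface:
#' shift(p) = k_C^eV * probe * sum_i delta_q_i / |p - r_i| (eV). The default
#' surface is two van der Waals radii from each heavy atom with a +0.1 e
#' probe. Shifts are exactly linear in the probe charge and antisymmetric
#' under its sign flip.
#'
#' @param mol Chromophore molecule tibble (site/ring labels recommended).
#' @param dq A [state_delta_charges()] with one entry per atom of `mol`.
#' @param probe Probe charge in e (non-zero).
#' @param scale Surface scale k (default 2).
#' @param density Surface point density, points per square Angstrom.
#' @param cloud Optionally, a pre-built (labelled) surface cloud; overrides
#'   `scale`/`density`.
#' @return An `estm_map`: the surface cloud with a `shift` column in eV and
#'   attributes `state`, `probe`.
#' @export
estm_map <- function(mol, dq, probe = 0.1, scale = 2, density = 1,
                     cloud = NULL) {
  stopifnot(inherits(dq, "state_delta_charges"))
  if (probe == 0) stop("Probe charge must be non-zero", call. = FALSE)
  if (length(dq$delta_q) != nrow(mol)) {
    stop("delta_q has ", length(dq$delta_q), " entries but molecule has ",
         nrow(mol), " atoms", call. = FALSE)
  }
  if (is.null(cloud)) {
    cloud <- assign_point_regions(generate_surface(mol, scale, density), mol)
  }
  pts <- as.matrix(cloud[, c("x", "y", "z")])
  pos <- coords_matrix(mol)
  shift <- numeric(nrow(pts))
  for (i in seq_len(nrow(mol))) {
    if (dq$delta_q[i] == 0) next
    d <- sqrt((pts[, 1] - pos[i, 1])^2 + (pts[, 2] - pos[i, 2])^2 +
                (pts[, 3] - pos[i, 3])^2)
    if (any(d <= 1e-6)) {
      stop("Surface point lies on atom ", mol$serial[i],
           "; cannot evaluate probe interaction", call. = FALSE)
    }
    shift <- shift + dq$delta_q[i] / d
  }
  out <- dplyr::mutate(cloud, shift = KC_EV * probe * shift)
  for (a in c("molecule", "scale", "density")) attr(out, a) <- attr(cloud, a)
  attr(out, "state") <- dq$state
  attr(out, "probe") <- probe
  class(out) <- c("estm_map", class(tibble::tibble()))
  out
}

#' First-order excitation-energy shift from an electrostatic environment
#'
#' Given the environment's potential at each chromophore atom (kT/e, e.g.
#' from [potential_at_atoms()] or a projected grid), the state's vertical
#' excitation energy shifts by
#' sum_i phi_i * delta_q_i * kT(T) (converted to eV). A uniform potential
#' shifts nothing because the difference charges sum to zero.
#'
#' @param mol Chromophore molecule (supplies the atom count).
#' @param dq A [state_delta_charges()].
#' @param phi_at_atoms Numeric vector, potential at each atom in kT/e.
#' @param temperature Temperature in kelvin fixing the kT scale.
#' @return Scalar shift in eV (positive = blue-shift).
#' @export
shift_from_environment <- function(mol, dq, phi_at_atoms,
                                   temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(dq, "state_delta_charges"))
  if (length(phi_at_atoms) != length(dq$delta_q) ||
      length(phi_at_atoms) != nrow(mol)) {
    stop("phi_at_atoms (", length(phi_at_atoms), "), delta_q (",
         length(dq$delta_q), ") and molecule atoms (", nrow(mol),
         ") must all agree in length", call. = FALSE)
  }
  sum(phi_at_atoms * dq$delta_q) * kT(temperature, unit = "eV")
}

#' Singlet-triplet gap shift induced by an environment
#'
#' Difference of the two state shifts, Delta(gap) = shift(Tn) - shift(S1):
#' positive values widen the singlet-triplet gap (the environment
#' destabilises the triplet and/or stabilises the singlet), negative values
#' narrow it.
#'
#' @param mol Chromophore molecule.
#' @param dq_S1,dq_Tn Difference-charge sets for the singlet and triplet.
#' @param phi_at_atoms Potential at each atom, kT/e.
#' @param temperature Kelvin.
#' @return Scalar gap shift in eV.
#' @export
gap_shift <- function(mol, dq_S1, dq_Tn, phi_at_atoms,
                      temperature = DEFAULT_TEMPERATURE) {
  shift_from_environment(mol, dq_Tn, phi_at_atoms, temperature) -
    shift_from_environment(mol, dq_S1, phi_at_atoms, temperature)
}

#' Gap report from a singlet/triplet map pair
#'
#' Scans a pair of tuning maps sharing one surface cloud for the maximum
#' red-shift of the singlet and the maximum blue-shift of the triplet. Their
#' combined magnitude is the probe's total capacity to widen the
#' singlet-triplet gap. When a map lacks the relevant sign the one-sided
#' extremum is reported and the result is flagged degenerate.
#'
#' @param map_S1,map_Tn `estm_map` objects on the same cloud.
#' @return A `gap_report` list: `max_redshift_S1` (eV, <= 0),
#'   `max_blueshift_Tn` (eV, >= 0), `combined_capacity` (eV), `degenerate`
#'   flag, and per-region gap-shift means `region_gap_means`.
#' @export
gap_report <- function(map_S1, map_Tn) {
  if (nrow(map_S1) != nrow(map_Tn) ||
      max(abs(as.matrix(map_S1[, c("x", "y", "z")]) -
              as.matrix(map_Tn[, c("x", "y", "z")]))) > 1e-9) {
    stop("The two maps must share one surface cloud", call. = FALSE)
  }
  min_s1 <- min(map_S1$shift)
  max_tn <- max(map_Tn$shift)
  degenerate <- !(min_s1 < 0 && max_tn > 0)
  max_red <- min(min_s1, 0)
  max_blue <- max(max_tn, 0)
  gaps <- map_Tn$shift - map_S1$shift
  region_means <- if ("region" %in% names(map_S1)) {
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(region = map_S1$region, gap = gaps),
                      .data$region),
      mean_gap_shift = mean(.data$gap), .groups = "drop")
  } else {
    tibble::tibble(region = character(0), mean_gap_shift = numeric(0))
  }
  structure(list(
    max_redshift_S1 = max_red,
    max_blueshift_Tn = max_blue,
    combined_capacity = abs(max_red) + max_blue,
    degenerate = degenerate,
    region_gap_means = region_means,
    states = c(attr(map_S1, "state"), attr(map_Tn, "state")),
    probe = attr(map_S1, "probe")
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n",
      "  max S1 red-shift:  ", format(x$max_redshift_S1, digits = 4), " eV\n",
      "  max Tn blue-shift: ", format(x$max_blueshift_Tn, digits = 4), " eV\n",
      "  combined capacity: ", format(x$combined_capacity, digits = 4), " eV",
      if (x$degenerate) "  (degenerate: one-sided)" else "", "\n", sep = "")
  invisible(x)
}
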