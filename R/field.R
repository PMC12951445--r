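# Classical point-charge electrostatics: the desk-scale stand-in for an
# external Poisson-Boltzmann solver. Potentials are returned in kT/e, the
# conventional unit of solver output, so projection maps built either way are
# directly comparable.

#' Field model parameters
#'
#' Uniform-dielectric, optionally Debye-screened Coulomb model:
#' phi(p) = k_C / (eps * kT) * sum_i q_i exp(-kappa d_i) / d_i, in kT/e.
#' With `kappa = 0` and `relative_dielectric = 1` this is the vacuum Coulomb
#' potential.
#'
#' @param relative_dielectric Relative dielectric constant, >= 1.
#' @param debye_kappa Inverse Debye screening length in 1/Angstrom, >= 0.
#' @param temperature Temperature in kelvin (sets the kT scale).
#' @return A `field_model` list.
#' @export
field_model <- function(relative_dielectric = 1, debye_kappa = 0,
                        temperature = DEFAULT_TEMPERATURE) {
  stopifnot(relative_dielectric >= 1, debye_kappa >= 0, temperature > 0)
  structure(list(relative_dielectric = relative_dielectric,
                 debye_kappa = debye_kappa,
                 temperature = temperature),
            class = "field_model")
}

#' Evaluate the potential of a charge set at points
#'
#' Brute-force pairwise sum (exactly testable; desk-scale n). An empty charge
#' set yields zeros. Errors if any evaluation point lies within 1e-6 Angstrom
#' of a charge.
#'
#' @param points m x 3 matrix, or a data frame with `x`, `y`, `z`, Angstrom.
#' @param charges A [charge_set()] tibble.
#' @param model A [field_model()].
#' @return Numeric vector of m potentials in kT/e.
#' @export
potential_at <- function(points, charges, model = field_model()) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  m <- nrow(points)
  if (nrow(charges) == 0) return(rep(0, m))
  prefac <- KC_KCAL / (model$relative_dielectric * kT(model$temperature))
  kappa <- model$debye_kappa
  phi <- numeric(m)
  cx <- charges$x; cy <- charges$y; cz <- charges$z; q <- charges$charge
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((points[, 1] - cx[i])^2 + (points[, 2] - cy[i])^2 +
                (points[, 3] - cz[i])^2)
    tooclose <- which(d <= 1e-6)
    if (length(tooclose) > 0) {
      stop("Evaluation point ", tooclose[1], " coincides with charge ", i,
           " (distance ", format(d[tooclose[1]], digits = 3),
           " A <= 1e-6 A)", call. = FALSE)
    }
    phi <- phi + if (kappa > 0) q[i] * exp(-kappa * d) / d else q[i] / d
  }
  prefac * phi
}

#' Evaluate a potential grid around a center
#'
#' Builds a node-centred cubic grid including both boundary planes (counts
#' per axis = box_edge / spacing + 1, so a 64 Angstrom box at 0.5 Angstrom
#' spacing has 129 x 129 x 129 = 2,146,689 nodes) and evaluates the charge
#' set's potential at every node.
#'
#' @param charges A [charge_set()].
#' @param box_edge Cube edge length in Angstrom.
#' @param spacing Node spacing in Angstrom; must divide `box_edge` exactly
#'   (tolerance 1e-9).
#' @param center Length-3 center of the box, Angstrom.
#' @param model A [field_model()].
#' @return A [potential_grid()] in kT/e.
#' @export
evaluate_grid <- function(charges, box_edge = 64, spacing = 0.5,
                          center = c(0, 0, 0), model = field_model()) {
  stopifnot(box_edge > 0, spacing > 0)
  steps <- box_edge / spacing
  if (abs(steps - round(steps)) > 1e-9) {
    stop("spacing ", spacing, " does not divide box_edge ", box_edge,
         " exactly", call. = FALSE)
  }
  n <- as.integer(round(steps)) + 1L
  origin <- center - box_edge / 2
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n) - 1) * spacing)
  if (nrow(charges) == 0) {
    return(potential_grid(origin, spacing, c(n, n, n),
                          array(0, dim = c(n, n, n))))
  }
  # accumulate per charge over the full node array (vectorised outer sums)
  prefac <- KC_KCAL / (model$relative_dielectric * kT(model$temperature))
  kappa <- model$debye_kappa
  vals <- array(0, dim = c(n, n, n))
  dx2 <- dy2 <- dz2 <- NULL
  for (i in seq_len(nrow(charges))) {
    dx2 <- (ax[[1]] - charges$x[i])^2
    dy2 <- (ax[[2]] - charges$y[i])^2
    dz2 <- (ax[[3]] - charges$z[i])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    if (any(d <= 1e-6)) {
      stop("Charge ", i, " coincides with a grid node; shift the grid center",
           call. = FALSE)
    }
    vals <- vals + if (kappa > 0) {
      charges$charge[i] * exp(-kappa * d) / d
    } else {
      charges$charge[i] / d
    }
  }
  potential_grid(origin, spacing, c(n, n, n), prefac * vals)
}

#' Potential at each atom of a molecule
#'
#' Convenience wrapper used by the environment-shift estimators: evaluates a
#' charge set's potential at every atom position.
#'
#' @param mol Molecule tibble.
#' @param charges A [charge_set()].
#' @param model A [field_model()].
#' @return Numeric vector, one kT/e value per atom of `mol`.
#' @export
potential_at_atoms <- function(mol, charges, model = field_model()) {
  potential_at(coords_matrix(mol), charges, model)
}
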