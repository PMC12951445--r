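#' Molecule tibbles
#'
#' A molecule is a tibble with one row per atom and columns
#' `serial` (integer), `name`, `element`, `residue_name`, `residue_id`
#' (integer), `chain`, `x`, `y`, `z` (Angstrom) and optionally `charge` (e),
#' `vdw_radius` (Angstrom), `site` (labelled chromophore site such as "N5",
#' `NA` otherwise) and `ring` (one of `"xylene"`, `"central"`, `"pyrimidine"`,
#' `"substituent"`). Plain PDB input has no charges or radii; PQR input has
#' both. All functions in the package accept and return this shape, so
#' molecules flow through dplyr pipelines unchanged.
#'
#' @param atoms A data frame with at least the coordinate and identity columns
#'   above.
#' @return A validated molecule tibble.
#' @export
as_molecule <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("serial", "name", "element", "residue_name", "residue_id",
                "chain", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("Molecule is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) {
    stop("Molecule has non-finite coordinates", call. = FALSE)
  }
  if ("vdw_radius" %in% names(atoms)) {
    bad <- !is.na(atoms$vdw_radius) & atoms$vdw_radius <= 0
    if (any(bad)) {
      stop("Non-positive vdw_radius for atom serial(s): ",
           paste(atoms$serial[bad], collapse = ", "), call. = FALSE)
    }
  }
  if ("ring" %in% names(atoms)) {
    known <- c("xylene", "central", "pyrimidine", "substituent")
    bad <- !is.na(atoms$ring) & !(atoms$ring %in% known)
    if (any(bad)) {
      stop("Unknown ring label(s): ",
           paste(unique(atoms$ring[bad]), collapse = ", "),
           "; expected one of ", paste(known, collapse = ", "), call. = FALSE)
    }
  }
  if ("site" %in% names(atoms)) {
    sites <- atoms$site[!is.na(atoms$site)]
    if (anyDuplicated(sites)) {
      stop("Duplicate site label(s): ",
           paste(unique(sites[duplicated(sites)]), collapse = ", "),
           call. = FALSE)
    }
  }
  atoms
}

#' Select the heavy atoms of a molecule
#'
#' Heavy atoms are all atoms whose element is not hydrogen or deuterium.
#' Surface generation, proximity analysis and projection all operate on heavy
#' atoms only.
#'
#' @param mol A molecule tibble.
#' @return The subset of rows with `element` not in `c("H", "D")`.
#' @export
heavy_atoms <- function(mol) {
  dplyr::filter(mol, !(toupper(.data$element) %in% c("H", "D")))
}

#' Total charge of a molecule or charge set
#'
#' @param x A tibble with a `charge` column.
#' @return The sum of charges in e.
#' @export
total_charge <- function(x) {
  if (!"charge" %in% names(x)) {
    stop("No charge column present", call. = FALSE)
  }
  sum(x$charge)
}

# Internal: n x 3 coordinate matrix of a molecule tibble.
coords_matrix <- function(mol) {
  m <- as.matrix(mol[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Construct a point-charge set
#'
#' A charge set is a tibble with columns `x`, `y`, `z` (Angstrom) and
#' `charge` (e), with an optional `label` attribute. It is the carrier for
#' protein environments, synthetic motifs and merged ASEC ensembles. An empty
#' charge set (zero rows) is valid and produces zero potential everywhere.
#'
#' @param positions An n x 3 matrix or a data frame with `x`, `y`, `z`.
#' @param charges Numeric vector of n charges in e.
#' @param label Optional name for the set.
#' @return A charge-set tibble.
#' @export
charge_set <- function(positions, charges = numeric(0), label = NULL) {
  if (is.data.frame(positions)) {
    stopifnot(all(c("x", "y", "z") %in% names(positions)))
    if (length(charges) == 0 && "charge" %in% names(positions)) {
      charges <- positions$charge
    }
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != length(charges)) {
    stop("positions and charges disagree in length", call. = FALSE)
  }
  if (length(charges) > 0 && (!all(is.finite(positions)) || !all(is.finite(charges)))) {
    stop("Charge set has non-finite values", call. = FALSE)
  }
  cs <- tibble::tibble(
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    charge = as.numeric(charges)
  )
  attr(cs, "label") <- label
  cs
}
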