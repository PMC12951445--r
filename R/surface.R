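# Scaled van der Waals surface sampling.
#
# Per heavy atom, candidate probe positions are laid out on a deterministic
# Fibonacci (golden-angle) spherical lattice at k * r_vdw, then candidates
# strictly inside any *other* heavy atom's k-scaled sphere are pruned. The
# same machinery serves spectral tuning maps (k = 2) and potential
# projections (k = 1).

# Deterministic golden-angle lattice of n unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a scaled van der Waals surface cloud
#'
#' Places points on a surface `scale` van der Waals radii from each heavy
#' atom, with per-atom counts proportional to the sphere area at that radius,
#' and removes candidates that fall strictly inside another heavy atom's
#' scaled sphere (tolerance 1e-9 Angstrom: points exactly on two spheres are
#' kept). Hydrogens neither seed nor prune. The lattice is deterministic, so
#' identical inputs give identical clouds.
#'
#' @param mol Molecule tibble; needs `vdw_radius` (assigned from the bundled
#'   table via [vdw_radius()] when absent).
#' @param scale Surface scale k > 0 (2 for tuning maps, 1 for projections).
#' @param density Target point density in points per square Angstrom.
#' @return A surface-cloud tibble with columns `x`, `y`, `z`,
#'   `parent` (row index in `mol`), `parent_serial`, and attributes
#'   `molecule`, `scale`, `density`.
#' @export
generate_surface <- function(mol, scale = 1, density = 1) {
  stopifnot(scale > 0, density > 0)
  if (!"vdw_radius" %in% names(mol) || anyNA(mol$vdw_radius)) {
    mol$vdw_radius <- vdw_radius(mol$element)
  }
  heavy_idx <- which(!(toupper(mol$element) %in% c("H", "D")))
  if (length(heavy_idx) == 0) {
    stop("Molecule has no heavy atoms; cannot generate a surface",
         call. = FALSE)
  }
  centers <- coords_matrix(mol)[heavy_idx, , drop = FALSE]
  radii <- scale * mol$vdw_radius[heavy_idx]
  pts <- vector("list", length(heavy_idx))
  for (a in seq_along(heavy_idx)) {
    n <- max(1L, as.integer(round(4 * pi * radii[a]^2 * density)))
    unit <- fibonacci_sphere(n)
    cand <- sweep(unit * radii[a], 2, centers[a, ], "+")
    keep <- rep(TRUE, n)
    for (b in seq_along(heavy_idx)) {
      if (b == a) next
      d2 <- (cand[, 1] - centers[b, 1])^2 + (cand[, 2] - centers[b, 2])^2 +
        (cand[, 3] - centers[b, 3])^2
      keep <- keep & d2 >= (radii[b] - 1e-9)^2
      if (!any(keep)) break
    }
    pts[[a]] <- tibble::tibble(
      x = cand[keep, 1], y = cand[keep, 2], z = cand[keep, 3],
      parent = heavy_idx[a],
      parent_serial = mol$serial[heavy_idx[a]]
    )
  }
  cloud <- dplyr::bind_rows(pts)
  if (nrow(cloud) == 0) {
    stop("All candidate surface points were pruned; decrease scale or check ",
         "the structure", call. = FALSE)
  }
  attr(cloud, "molecule") <- mol
  attr(cloud, "scale") <- scale
  attr(cloud, "density") <- density
  cloud
}

#' Label surface points by chromophore region
#'
#' Each point inherits its parent atom's ring label (`region`) and, when the
#' parent is a labelled site (N5, C4, ...), the site name (`site`). The
#' composite faces used in tuning analysis, "N5/C4" and "C2/N3", are exposed
#' as logical columns `face_N5_C4` and `face_C2_N3` (unions of the two site
#' point sets).
#'
#' @param cloud A surface cloud from [generate_surface()].
#' @param mol Optional molecule with `site`/`ring` columns; defaults to the
#'   cloud's source molecule.
#' @return The cloud with `region`, `site`, `face_N5_C4`, `face_C2_N3`
#'   columns added.
#' @export
assign_point_regions <- function(cloud, mol = attr(cloud, "molecule")) {
  stopifnot(!is.null(mol))
  ring <- if ("ring" %in% names(mol)) mol$ring else rep(NA_character_, nrow(mol))
  site <- if ("site" %in% names(mol)) mol$site else rep(NA_character_, nrow(mol))
  ring[is.na(ring)] <- "substituent"
  out <- dplyr::mutate(
    cloud,
    region = ring[.data$parent],
    site = site[.data$parent],
    face_N5_C4 = .data$site %in% c("N5", "C4"),
    face_C2_N3 = .data$site %in% c("C2", "N3")
  )
  for (a in c("molecule", "scale", "density")) {
    attr(out, a) <- attr(cloud, a)
  }
  out
}

#' Export a surface cloud (or value map) for external rendering
#'
#' Writes a CSV (`x, y, z, parent_serial, region`, plus any value columns)
#' and, optionally, a pseudo-atom PDB with a chosen column in the B-factor
#' field, the conventional route into molecular graphics programs.
#'
#' @param cloud Surface cloud tibble (regions optional).
#' @param csv Path of the CSV to write, or `NULL` to skip.
#' @param pdb Path of the pseudo-atom PDB to write, or `NULL` to skip.
#' @param bfactor_column Column written to the PDB B-factor field.
#' @return Named list of written paths, invisibly.
#' @export
export_cloud <- function(cloud, csv = NULL, pdb = NULL,
                         bfactor_column = NULL) {
  written <- list()
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(cloud), csv, row.names = FALSE)
    written$csv <- csv
  }
  if (!is.null(pdb)) {
    b <- if (!is.null(bfactor_column)) cloud[[bfactor_column]] else 0
    pseudo <- tibble::tibble(
      serial = seq_len(nrow(cloud)), name = "PS", element = "He",
      residue_name = "SUR", residue_id = 1L, chain = "S",
      x = cloud$x, y = cloud$y, z = cloud$z
    )
    write_pdb(pseudo, pdb, bfactor = rep_len(b, nrow(cloud)))
    written$pdb <- pdb
  }
  invisible(written)
}
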