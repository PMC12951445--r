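# Synthetic fixtures: a toy flavin chromophore, qualitative state
# difference-charge sets, LOV1-like / LOV2-like point-charge environments,
# and seeded trajectories with prescribed per-residue fluctuations. These
# stand in for the quantum-chemistry and molecular-dynamics engines so the
# whole pipeline runs at desk scale; they are declared synthetic throughout
# and emulate qualitative structure, never published per-point values.

#' Build the toy flavin chromophore
#'
#' A planar, linearly fused tricyclic heavy-atom skeleton in the isoalloxazine
#' layout: a xylene-type ring (left), a central pyrazine ring with N5 (top)
#' and N10 (bottom), and a pyrimidine ring with C4/O4 (top) and N1/C2/O2
#' (bottom edge), plus a methyl carbon on N10 (lumiflavin-style). Idealised
#' 1.4 Angstrom ring bonds, all atoms in the z = 0 plane; 17 heavy atoms.
#' Sites N1, C2, N3, C4, C4a, N5, N10, O2, O4 are labelled; bridgehead atoms
#' (C4a, C10a, C5a, C9a) are assigned to the central ring in the
#' one-label-per-atom ring partition.
#'
#' @return A molecule tibble with `site`, `ring`, `charge` (0) and
#'   `vdw_radius` columns.
#' @export
make_toy_flavin <- function() {
  a <- 1.4                     # ring bond length, Angstrom
  hx <- a * sqrt(3) / 2        # hexagon half-width
  cx <- 2 * hx                 # ring-center spacing
  atom <- function(name, element, x, y, site = NA_character_, ring) {
    tibble::tibble(name = name, element = element, x = x, y = y,
                   site = site, ring = ring)
  }
  df <- dplyr::bind_rows(
    # xylene ring (left, centered at -cx): unique vertices
    atom("C6", "C", -cx, a, ring = "xylene"),
    atom("C7", "C", -cx - hx, a / 2, ring = "xylene"),
    atom("C8", "C", -cx - hx, -a / 2, ring = "xylene"),
    atom("C9", "C", -cx, -a, ring = "xylene"),
    # central (pyrazine) ring, centered at origin; bridgeheads included
    atom("C5A", "C", -hx, a / 2, ring = "central"),
    atom("C9A", "C", -hx, -a / 2, ring = "central"),
    atom("N5", "N", 0, a, site = "N5", ring = "central"),
    atom("N10", "N", 0, -a, site = "N10", ring = "central"),
    atom("C4A", "C", hx, a / 2, site = "C4a", ring = "central"),
    atom("C10A", "C", hx, -a / 2, ring = "central"),
    # pyrimidine ring (right, centered at +cx): unique vertices
    atom("C4", "C", cx, a, site = "C4", ring = "pyrimidine"),
    atom("N3", "N", cx + hx, a / 2, site = "N3", ring = "pyrimidine"),
    atom("C2", "C", cx + hx, -a / 2, site = "C2", ring = "pyrimidine"),
    atom("N1", "N", cx, -a, site = "N1", ring = "pyrimidine"),
    # carbonyl oxygens and the N10 methyl
    atom("O4", "O", cx, a + 1.23, site = "O4", ring = "substituent"),
    atom("O2", "O", cx + hx + 1.23 * sqrt(3) / 2, -a / 2 - 1.23 / 2,
         site = "O2", ring = "substituent"),
    atom("C10M", "C", 0, -a - 1.45, ring = "substituent")
  )
  mol <- tibble::tibble(
    serial = seq_len(nrow(df)), name = df$name, element = df$element,
    residue_name = "LFN", residue_id = 1L, chain = "A",
    x = df$x, y = df$y, z = 0,
    charge = 0, vdw_radius = vdw_radius(df$element),
    site = df$site, ring = df$ring
  )
  as_molecule(mol)
}

#' Synthetic state difference-charge sets
#'
#' Zero-sum per-atom difference charges for the toy flavin encoding the
#' qualitative tuning structure of the two photophysically relevant states:
#'
#' * `"S1_pipi"` (bright singlet): negative difference charge on N5, C4 and
#'   the lower edge of the central/pyrimidine rings (N10, C10a, N1, C2), so
#'   a positive probe there red-shifts the state; compensation is positive
#'   on the xylene-side atoms, so a positive probe there blue-shifts it.
#' * `"Tn_npi"` (dark triplet, N5 lone pair): positive difference charge on
#'   N5 (and weakly C4), so a positive probe near N5 blue-shifts the
#'   triplet; compensation is spread over the xylene ring.
#'
#' Magnitudes (0.02-0.10 e) are chosen so toy map extrema at a +0.1 e probe
#' on the 2x van der Waals surface land at order 0.01-0.05 eV. These sets
#' are qualitative synthetic stand-ins, not fits to any computed map.
#'
#' @param state `"S1_pipi"` or `"Tn_npi"`.
#' @param mol The toy flavin (defaults to [make_toy_flavin()]).
#' @return A [state_delta_charges()] object.
#' @export
make_delta_charges <- function(state = c("S1_pipi", "Tn_npi"),
                               mol = make_toy_flavin()) {
  state <- match.arg(state)
  dq <- stats::setNames(rep(0, nrow(mol)), mol$name)
  if (state == "S1_pipi") {
    dq[c("N5", "C4")] <- -0.05
    dq[c("N10", "N1")] <- -0.03
    dq[c("C10A", "C2")] <- -0.02
    minus_total <- sum(dq)
    comp <- c("C6", "C7", "C8", "C9", "C5A", "C9A")
    dq[comp] <- -minus_total / length(comp)
  } else {
    dq["N5"] <- 0.10
    dq["C4"] <- 0.04
    comp <- c("C6", "C7", "C8", "C9")
    dq[comp] <- -sum(dq) / length(comp)
  }
  state_delta_charges(state, unname(dq))
}

#' Synthetic point-charge environments
#'
#' Minimal protein-like electrostatic motifs around the toy flavin:
#'
#' * `"LOV1_like"`: a single positive charge `magnitude` placed `distance`
#'   Angstrom below (negative z) the midpoint of the N5/C4 face, emulating
#'   the conserved positive potential LOV1 domains project onto that face.
#' * `"LOV2_like"`: a negative charge at the same site plus a diffuse
#'   negative shell (one -0.05 e point `distance` Angstrom below each xylene
#'   ring atom), emulating the more negative, diffuse LOV2 projection.
#' * `"neutral"`: the empty set (zero potential everywhere downstream).
#'
#' @param motif `"LOV1_like"`, `"LOV2_like"` or `"neutral"`.
#' @param mol The toy flavin.
#' @param distance Offset below the molecular plane, Angstrom.
#' @param magnitude Charge magnitude at the N5/C4 face, e.
#' @return A [charge_set()].
#' @export
make_environment <- function(motif = c("LOV1_like", "LOV2_like", "neutral"),
                             mol = make_toy_flavin(), distance = 3.0,
                             magnitude = 0.5) {
  motif <- match.arg(motif)
  if (motif == "neutral") {
    return(charge_set(matrix(numeric(0), ncol = 3), numeric(0),
                      label = "neutral"))
  }
  n5 <- as.numeric(mol[which(mol$site == "N5"), c("x", "y", "z")])
  c4 <- as.numeric(mol[which(mol$site == "C4"), c("x", "y", "z")])
  face <- (n5 + c4) / 2 - c(0, 0, distance)
  if (motif == "LOV1_like") {
    return(charge_set(matrix(face, ncol = 3), magnitude, label = "LOV1_like"))
  }
  xy <- dplyr::filter(mol, .data$ring == "xylene")
  shell <- cbind(xy$x, xy$y, xy$z - distance)
  charge_set(rbind(face, shell), c(-magnitude, rep(-0.05, nrow(shell))),
             label = "LOV2_like")
}

#' Synthetic trajectory with prescribed per-residue fluctuations
#'
#' Builds a compact globular alpha-carbon arrangement of `n_residues`
#' residues (one CA per residue, laid out on a spherical Fibonacci shell
#' whose radius gives a 3.8 Angstrom nearest-neighbour spacing, emulating a
#' folded domain rather than an extended chain) and emulates dynamics by
#' adding independent per-frame, per-axis Gaussian displacements with
#' per-residue standard deviation `sigma` (Angstrom).
#' Optionally each frame is additionally subjected to a random global rigid
#' motion (off by default, isolating fluctuation recovery from superposition
#' quality). The expected recovered RMSF of residue r is sigma_r * sqrt(3).
#' Deterministic for a fixed seed.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param sigma Per-residue per-axis displacement sd, Angstrom; scalar or
#'   length `n_residues`.
#' @param dt Frame spacing in ps (times are `dt, 2 dt, ...`).
#' @param rigid_jitter If `TRUE`, apply a random rigid rotation+translation
#'   per frame.
#' @param charge Per-atom charge assigned to the topology (for ASEC tests).
#' @param seed Integer RNG seed.
#' @return A trajectory.
#' @export
make_trajectory <- function(n_residues = 10, n_frames = 100, sigma = 0.3,
                            dt = 50, rigid_jitter = FALSE, charge = 0,
                            seed = 1) {
  stopifnot(n_residues >= 1, n_frames >= 1, all(sigma > 0) || all(sigma == 0))
  sigma <- rep_len(sigma, n_residues)
  i <- seq_len(n_residues)
  # compact shell: radius set so neighbouring CAs sit ~3.8 A apart
  radius <- max(2.3, 3.8 * sqrt(n_residues / (4 * pi)))
  base <- fibonacci_sphere(n_residues) * radius
  topo <- tibble::tibble(
    serial = i, name = "CA", element = "C",
    residue_name = "ALA", residue_id = i, chain = "A",
    x = base[, 1], y = base[, 2], z = base[, 3],
    charge = rep_len(charge, n_residues)
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    noise <- matrix(stats::rnorm(n_residues * 3), ncol = 3) * sigma
    f <- base + noise
    if (rigid_jitter) {
      ang <- stats::runif(3, -pi, pi)
      rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                     sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
      ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                     -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
      f <- f %*% t(rz %*% ry) +
        matrix(stats::runif(3, -2, 2), n_residues, 3, byrow = TRUE)
    }
    f
  })
  trajectory(topo, frames, times = dt * seq_len(n_frames))
}

# Save/restore the global RNG state so generators are seeded locally.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic protein shell around the toy flavin
#'
#' Places `n_residues` single-heavy-atom pseudo-residues on a sphere of
#' staggered radii around the chromophore centroid (radii
#' `r_min + (i - 1) * r_step`), for exercising proximity selection with a
#' known answer.
#'
#' @param mol The chromophore.
#' @param n_residues Number of pseudo-residues.
#' @param r_min,r_step Radial placement parameters, Angstrom.
#' @param seed RNG seed for sphere directions.
#' @return A molecule tibble with one atom per residue.
#' @export
make_residue_shell <- function(mol = make_toy_flavin(), n_residues = 20,
                               r_min = 2.5, r_step = 0.5, seed = 1) {
  centroid <- colMeans(coords_matrix(heavy_atoms(mol)))
  dirs <- fibonacci_sphere(n_residues)
  radii <- r_min + (seq_len(n_residues) - 1) * r_step
  pos <- sweep(dirs * radii, 2, centroid, "+")
  as_molecule(tibble::tibble(
    serial = seq_len(n_residues), name = "CB", element = "C",
    residue_name = "GLY", residue_id = seq_len(n_residues), chain = "B",
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  ))
}
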