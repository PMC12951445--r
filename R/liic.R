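# Linear interpolation / extrapolation in Cartesian coordinates: the
# 1D reaction-path abscissa between two optimised geometries. Energies along
# the path are left to an external electronic-structure engine.

#' Build a linear-interpolation Cartesian path
#'
#' Interpolates `n_interp` geometries between A (t = 0) and B
#' (t = n_interp - 1), G_t = A + t * (B - A) / (n_interp - 1), and continues
#' the same step `n_extrap_each` geometries beyond both ends. The defaults
#' (15 + 2 x 3) give 21 geometries. Endpoints are reproduced exactly and
#' consecutive geometry differences are identical.
#'
#' @param geomA,geomB Molecule tibbles or n x 3 matrices with matching atom
#'   counts and ordering.
#' @param n_interp Number of interpolated geometries including both
#'   endpoints (>= 2).
#' @param n_extrap_each Extrapolated geometries added beyond each end.
#' @param prealign If `TRUE`, rigid-body superpose B onto A before
#'   interpolating (off by default: geometries from one protein frame are
#'   already aligned).
#' @return An `liic_path` list: `geometries` (list of n x 3 matrices),
#'   `coordinate` (step units; 0 at A, n_interp - 1 at B, negative before A),
#'   `endpoints` (indices of A and B in the list), `elements`.
#' @export
build_path <- function(geomA, geomB, n_interp = 15, n_extrap_each = 3,
                       prealign = FALSE) {
  stopifnot(n_interp >= 2, n_extrap_each >= 0)
  elements <- NULL
  if (is.data.frame(geomA)) {
    if (is.data.frame(geomB) &&
        (nrow(geomA) != nrow(geomB) ||
         !all(geomA$serial == geomB$serial))) {
      stop("Endpoint geometries disagree in atoms/ordering; reorder both by ",
           "serial before building the path", call. = FALSE)
    }
    elements <- geomA$element
    geomA <- coords_matrix(geomA)
  }
  if (is.data.frame(geomB)) geomB <- coords_matrix(geomB)
  geomA <- as.matrix(geomA); geomB <- as.matrix(geomB)
  if (!all(dim(geomA) == dim(geomB))) {
    stop("Endpoint geometries disagree in atom count (", nrow(geomA), " vs ",
         nrow(geomB), "); reorder/match atoms by serial", call. = FALSE)
  }
  if (prealign) geomB <- kabsch(geomB, geomA)
  step <- (geomB - geomA) / (n_interp - 1)
  ts <- seq(-n_extrap_each, n_interp - 1 + n_extrap_each)
  geoms <- lapply(ts, function(t) geomA + t * step)
  # endpoints bit-identical to the inputs
  geoms[[which(ts == 0)]] <- geomA
  geoms[[which(ts == n_interp - 1)]] <- geomB
  structure(list(
    geometries = geoms,
    coordinate = ts,
    endpoints = c(which(ts == 0), which(ts == n_interp - 1)),
    elements = elements
  ), class = "liic_path")
}

#' @export
print.liic_path <- function(x, ...) {
  cat("<liic_path> ", length(x$geometries), " geometries, coordinate ",
      min(x$coordinate), " .. ", max(x$coordinate),
      " (endpoints at ", paste(x$endpoints, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Per-step displacement metrics of a path
#'
#' RMS and maximum per-atom displacement between consecutive geometries.
#' Linearity makes these constant along the path; the spread across steps is
#' reported as a consistency check.
#'
#' @param path An `liic_path`.
#' @return A list: `rms_step` (Angstrom), `max_atom_step` (Angstrom),
#'   `per_step` tibble (`step`, `rms`, `max`), `uniform` (TRUE when all
#'   steps agree to 1e-9).
#' @export
path_metrics <- function(path) {
  g <- path$geometries
  if (length(g) < 2) {
    return(list(rms_step = 0, max_atom_step = 0,
                per_step = tibble::tibble(step = integer(0), rms = numeric(0),
                                          max = numeric(0)),
                uniform = TRUE))
  }
  per <- purrr::map_dfr(seq_len(length(g) - 1), function(k) {
    d <- g[[k + 1]] - g[[k]]
    dn <- sqrt(rowSums(d^2))
    tibble::tibble(step = k, rms = sqrt(mean(dn^2)), max = max(dn))
  })
  list(rms_step = mean(per$rms), max_atom_step = max(per$max),
       per_step = per,
       uniform = (max(per$rms) - min(per$rms)) <= 1e-9)
}

#' Tidy a path into a long tibble
#'
#' @param x An `liic_path`.
#' @param ... Unused.
#' @return Tibble with `geometry`, `coordinate`, `atom`, `x`, `y`, `z`.
#' @exportS3Method generics::tidy
#' @export
tidy.liic_path <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$geometries), x$coordinate, function(k, t0) {
    g <- x$geometries[[k]]
    tibble::tibble(geometry = k, coordinate = t0, atom = seq_len(nrow(g)),
                   x = g[, 1], y = g[, 2], z = g[, 3])
  })
}

#' Write a path as per-geometry XYZ files plus a manifest
#'
#' One XYZ file per geometry (`path_###.xyz`) and a CSV manifest
#' (`index, coordinate, filename`), ready for an external energy engine.
#'
#' @param path An `liic_path` with `elements` set (built from molecules).
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return The manifest tibble, invisibly.
#' @export
write_path_xyz <- function(path, dir, prefix = "path") {
  if (is.null(path$elements)) {
    stop("Path has no element symbols; build it from molecule tibbles to ",
         "write XYZ", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.xyz", prefix, seq_along(path$geometries))
  for (k in seq_along(path$geometries)) {
    write_xyz(path$geometries[[k]], file.path(dir, files[k]),
              elements = path$elements,
              comment = sprintf("coordinate = %g", path$coordinate[k]))
  }
  manifest <- tibble::tibble(index = seq_along(path$geometries),
                             coordinate = path$coordinate,
                             filename = files)
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
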