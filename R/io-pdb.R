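# PDB fixed-width reader/writer.
#
# Columns follow the PDB v3.3 ATOM/HETATM layout. Serial (cols 7-11) and
# residue id (cols 23-26) fields that overflow their width are decoded with
# the hybrid-36 convention used by large-structure tools.

# Decode a hybrid-36 field of the given width; returns NA for undecodable.
hy36_decode <- function(field, width) {
  field <- trimws(field)
  out <- suppressWarnings(as.integer(field))
  need <- is.na(out) & nzchar(field)
  if (any(need)) {
    dec <- function(s) {
      first <- substr(s, 1, 1)
      v <- strtoi(toupper(s), base = 36L)
      if (is.na(v)) return(NA_integer_)
      if (grepl("^[A-Z]", s)) {
        as.integer(v - 10L * 36L^(width - 1L) + 10L^width)
      } else if (grepl("^[a-z]", s)) {
        as.integer(v - 10L * 36L^(width - 1L) + 10L^width + 26L * 36L^(width - 1L))
      } else {
        NA_integer_
      }
    }
    out[need] <- vapply(field[need], dec, integer(1))
  }
  out
}

parse_atom_records <- function(lines, lineno, path) {
  sub_f <- function(a, b) substr(lines, a, b)
  num <- function(a, b, what) {
    raw <- trimws(sub_f(a, b))
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v)
    if (any(bad)) {
      stop("Malformed PDB record in '", path, "' at line ", lineno[bad][1],
           ": cannot parse ", what, " field '", raw[bad][1], "'",
           call. = FALSE)
    }
    v
  }
  serial <- hy36_decode(sub_f(7, 11), 5L)
  resid <- hy36_decode(sub_f(23, 26), 4L)
  if (anyNA(serial)) {
    stop("Malformed PDB record in '", path, "' at line ",
         lineno[is.na(serial)][1], ": cannot parse atom serial field '",
         trimws(substr(lines[is.na(serial)][1], 7, 11)), "'", call. = FALSE)
  }
  if (anyNA(resid)) {
    stop("Malformed PDB record in '", path, "' at line ",
         lineno[is.na(resid)][1], ": cannot parse residue id field '",
         trimws(substr(lines[is.na(resid)][1], 23, 26)), "'", call. = FALSE)
  }
  name <- trimws(sub_f(13, 16))
  element <- trimws(sub_f(77, 78))
  # Fall back to the first letter of the atom name when the element column
  # is blank (common in hand-written files).
  blank <- !nzchar(element)
  element[blank] <- gsub("[^A-Za-z].*$", "", name[blank])
  element[blank] <- toupper(substr(element[blank], 1, 1))
  tibble::tibble(
    serial = serial,
    name = name,
    element = element,
    residue_name = trimws(sub_f(18, 20)),
    residue_id = resid,
    chain = trimws(sub_f(22, 22)),
    x = num(31, 38, "x"),
    y = num(39, 46, "y"),
    z = num(47, 54, "z"),
    bfactor = suppressWarnings(as.numeric(trimws(sub_f(61, 66))))
  )
}

#' Read a PDB file
#'
#' Parses fixed-width ATOM/HETMEM records into a molecule tibble, preserving
#' atom order. Residue ids and serials beyond the field width are decoded via
#' the hybrid-36 convention. Plain PDB carries no charges or radii; use
#' [read_pqr()] for charged structures. Multi-model files (MODEL/ENDMDL) are
#' returned as a trajectory when `multi_model = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param multi_model If `TRUE`, parse MODEL blocks into a
#'   [trajectory()]; frame times default to the model index in ps.
#' @return A molecule tibble, or a trajectory when `multi_model = TRUE`.
#' @export
read_pdb <- function(path, multi_model = FALSE) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    grepl("^(ATOM|HETATM)", rec)
  model_starts <- grepl("^MODEL", lines)
  if (!multi_model || !any(model_starts)) {
    keep <- which(is_atom)
    if (any(model_starts)) {
      # single-molecule read of a multi-model file: first model only
      first_end <- which(grepl("^ENDMDL", lines))[1]
      if (!is.na(first_end)) keep <- keep[keep < first_end]
    }
    if (length(keep) == 0) stop("No ATOM/HETATM records in '", path, "'",
                                call. = FALSE)
    mol <- parse_atom_records(lines[keep], keep, path)
    if (multi_model) {
      return(trajectory(mol, list(coords_matrix(mol)), times = 1))
    }
    return(as_molecule(mol))
  }
  bounds <- which(model_starts)
  ends <- which(grepl("^ENDMDL", lines))
  frames <- vector("list", length(bounds))
  topo <- NULL
  for (k in seq_along(bounds)) {
    to <- if (k <= length(ends)) ends[k] else length(lines)
    idx <- which(is_atom & seq_along(lines) > bounds[k] & seq_along(lines) < to)
    mol <- parse_atom_records(lines[idx], idx, path)
    if (is.null(topo)) topo <- mol
    if (nrow(mol) != nrow(topo)) {
      stop("Model ", k, " in '", path, "' has ", nrow(mol),
           " atoms; expected ", nrow(topo), call. = FALSE)
    }
    frames[[k]] <- coords_matrix(mol)
  }
  trajectory(as_molecule(topo), frames, times = seq_along(frames))
}

format_pdb_line <- function(mol, bfactor = NULL, hetatm = FALSE) {
  n <- nrow(mol)
  b <- if (is.null(bfactor)) rep(0, n) else bfactor
  occ <- rep(1, n)
  rectype <- if (hetatm) "HETATM" else "ATOM  "
  name <- ifelse(nchar(mol$name) < 4, paste0(" ", mol$name), mol$name)
  sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, mol$serial %% 100000L, substr(name, 1, 4),
          substr(mol$residue_name, 1, 3),
          substr(paste0(mol$chain, " "), 1, 1), mol$residue_id %% 10000L,
          mol$x, mol$y, mol$z, occ, b, toupper(substr(mol$element, 1, 2)))
}

#' Write a molecule (or trajectory) to PDB
#'
#' @param mol A molecule tibble or a trajectory.
#' @param path Output path.
#' @param bfactor Optional numeric vector (one per atom) written into the
#'   B-factor column at 2 decimal places.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mol, path, bfactor = NULL) {
  if (is_trajectory(mol)) {
    traj <- mol
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(traj$frames)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      m <- traj$topology
      m$x <- traj$frames[[k]][, 1]
      m$y <- traj$frames[[k]][, 2]
      m$z <- traj$frames[[k]][, 3]
      writeLines(format_pdb_line(m, bfactor), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  lines <- c(format_pdb_line(mol, bfactor), "END")
  writeLines(lines, path)
  invisible(path)
}
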