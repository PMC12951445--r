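# PQR reader/writer. PQR records are whitespace-delimited (the convention of
# PDB->PQR converters feeding Poisson-Boltzmann solvers), not fixed-width:
#   ATOM serial name resName [chain] resId x y z charge radius

#' Read a PQR file
#'
#' Whitespace-delimited ATOM/HETATM records with per-atom charge (e) and van
#' der Waals radius (Angstrom) in the last two fields. The chain column is
#' optional, as emitted by common converters.
#'
#' @param path Path to a PQR file.
#' @return A molecule tibble with `charge` and `vdw_radius` columns.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("No ATOM/HETATM records in '", path, "'",
                             call. = FALSE)
  parse_one <- function(line, lineno) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    # with chain: 11 fields; without: 10
    if (length(f) == 11) {
      chain <- f[5]; rest <- f[6:11]
    } else if (length(f) == 10) {
      chain <- ""; rest <- f[5:10]
    } else {
      stop("Malformed PQR record in '", path, "' at line ", lineno,
           ": expected 10 or 11 fields (missing charge/radius column?), got ",
           length(f), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(rest))
    if (anyNA(vals) || is.na(suppressWarnings(as.integer(f[2])))) {
      stop("Malformed PQR record in '", path, "' at line ", lineno,
           ": non-numeric field", call. = FALSE)
    }
    tibble::tibble(
      serial = as.integer(f[2]), name = f[3],
      element = guess_element(f[3]),
      residue_name = f[4], residue_id = as.integer(vals[1]), chain = chain,
      x = vals[2], y = vals[3], z = vals[4],
      charge = vals[5], vdw_radius = vals[6]
    )
  }
  mol <- purrr::map2_dfr(lines[idx], idx, parse_one)
  as_molecule(mol)
}

# Element from an atom name: strip digits, take leading letters; two-letter
# elements only when the full name matches a known two-letter symbol.
guess_element <- function(name) {
  vapply(name, function(nm) {
    letters_only <- gsub("[^A-Za-z].*$", "", nm)
    two <- toupper(substr(letters_only, 1, 2))
    if (nchar(letters_only) >= 2 &&
        two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")) {
      return(two)
    }
    toupper(substr(letters_only, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Write a molecule to PQR
#'
#' @param mol A molecule tibble with `charge` and `vdw_radius` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(mol, path) {
  if (!all(c("charge", "vdw_radius") %in% names(mol))) {
    stop("Molecule needs charge and vdw_radius columns to write PQR",
         call. = FALSE)
  }
  chain <- ifelse(is.na(mol$chain) | mol$chain == "", "", paste0(mol$chain, " "))
  lines <- sprintf("ATOM %d %s %s %s%d %.6f %.6f %.6f %.6f %.6f",
                   mol$serial, mol$name, mol$residue_name, chain,
                   mol$residue_id, mol$x, mol$y, mol$z,
                   mol$charge, mol$vdw_radius)
  writeLines(lines, path)
  invisible(path)
}
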