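# Bundled van der Waals radii (Angstrom), Amber/Bondi-style values as used by
# common PDB->PQR converters. Overridable in vdw_radius() and in readers that
# assign radii.
.vdw_table <- c(
  H  = 1.20, D  = 1.20, C  = 1.70, N  = 1.55, O  = 1.52, S  = 1.80,
  P  = 1.80, F  = 1.47, CL = 1.75, BR = 1.85, I  = 1.98,
  NA. = 2.27, K  = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.40,
  MN = 1.40, CU = 1.40, SE = 1.90, B = 1.92
)
names(.vdw_table)[names(.vdw_table) == "NA."] <- "NA"

#' Van der Waals radius lookup
#'
#' Returns the van der Waals radius for an element symbol from a single
#' bundled Amber/Bondi-style table. The table can be overridden (entirely or
#' per element) with a named numeric vector, e.g. when matching the radius set
#' of a specific force field.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @param table Optional named numeric vector of radii in Angstrom; entries
#'   override or extend the bundled table.
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius("C")
#' vdw_radius(c("N", "O"), table = c(N = 1.6))
vdw_radius <- function(element, table = NULL) {
  tab <- .vdw_table
  if (!is.null(table)) {
    stopifnot(is.numeric(table), !is.null(names(table)))
    tab[toupper(names(table))] <- table
  }
  key <- toupper(element)
  r <- unname(tab[key])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    stop("Unknown element symbol(s): ", paste(unknown, collapse = ", "),
         "; known symbols: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  }
  if (any(r <= 0)) stop("Radius table contains non-positive radii", call. = FALSE)
  r
}

#' Read a van der Waals radius table from file
#'
#' Two-column whitespace-delimited text: element symbol, radius in Angstrom.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the table file.
#' @return Named numeric vector suitable for the `table` argument of
#'   [vdw_radius()].
#' @export
read_radius_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("element", "radius"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$radius), toupper(df$element))
}
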