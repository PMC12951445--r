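# OpenDX scalar-grid I/O in the "gridpositions counts" dialect written by
# Poisson-Boltzmann solvers. Values are stored z-fastest.

#' Potential grids
#'
#' A regular 3D scalar field (values conventionally in kT/e) with an origin,
#' per-axis spacing and per-axis node counts. Stored as a list with a 3D
#' `values` array indexed `[ix, iy, iz]`.
#'
#' @param origin Numeric length-3, Angstrom.
#' @param spacing Numeric length-3 (or scalar), Angstrom, all > 0.
#' @param counts Integer length-3, nodes per axis.
#' @param values Numeric array of dim `counts`, or a vector of
#'   `prod(counts)` values in z-fastest order.
#' @return An object of class `potential_grid`.
#' @export
potential_grid <- function(origin, spacing, counts, values) {
  origin <- as.numeric(origin)
  spacing <- rep_len(as.numeric(spacing), 3L)
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3, length(counts) == 3)
  if (any(spacing <= 0)) stop("Grid spacing must be positive on all axes",
                              call. = FALSE)
  if (any(counts < 1)) stop("Grid counts must be positive", call. = FALSE)
  n <- prod(counts)
  if (is.array(values) && length(dim(values)) == 3) {
    if (!all(dim(values) == counts)) {
      stop("values array dimensions ", paste(dim(values), collapse = "x"),
           " do not match counts ", paste(counts, collapse = "x"),
           call. = FALSE)
    }
  } else {
    if (length(values) != n) {
      stop("Expected ", n, " grid values, got ", length(values), call. = FALSE)
    }
    # z-fastest vector -> array[ix, iy, iz]
    values <- aperm(array(as.numeric(values), dim = rev(counts)), 3:1)
  }
  structure(list(origin = origin, spacing = spacing, counts = counts,
                 values = values),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat("<potential_grid> ", paste(x$counts, collapse = " x "),
      " nodes (", prod(x$counts), "), spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " A, origin ",
      paste(signif(x$origin, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Node coordinates along one axis.
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$counts[axis]) - 1) * grid$spacing[axis]
}

#' Tidy a potential grid into a long tibble
#'
#' @param x A `potential_grid`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `z`, `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.potential_grid <- function(x, ...) {
  ax <- lapply(1:3, function(a) grid_axis(x, a))
  g <- expand.grid(ix = seq_len(x$counts[1]), iy = seq_len(x$counts[2]),
                   iz = seq_len(x$counts[3]))
  tibble::tibble(
    x = ax[[1]][g$ix], y = ax[[2]][g$iy], z = ax[[3]][g$iz],
    value = as.numeric(x$values[cbind(g$ix, g$iy, g$iz)])
  )
}

#' Write a potential grid to an OpenDX file
#'
#' Emits the `gridpositions counts` dialect with z-fastest value ordering,
#' three values per line, as Poisson-Boltzmann solvers do, so outputs are
#' interchangeable with solver-generated maps.
#'
#' @param grid A `potential_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"))
  n <- prod(grid$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by flavotune",
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$counts[1], grid$counts[2], grid$counts[3]),
    sprintf("origin %.6e %.6e %.6e",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e %.6e %.6e", grid$spacing[1], 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, grid$spacing[2], 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$counts[1], grid$counts[2], grid$counts[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # z-fastest flattening
  v <- as.numeric(aperm(grid$values, 3:1))
  pad <- (3 - length(v) %% 3) %% 3
  vm <- matrix(c(sprintf("%.10e", v), rep("", pad)), nrow = 3)
  writeLines(trimws(apply(vm, 2, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Accepts grids written by [write_dx()] or by external Poisson-Boltzmann
#' solvers (same `gridpositions counts` dialect, z-fastest data).
#'
#' @param path Path to a `.dx` file.
#' @return A `potential_grid`.
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  cl <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(cl) == 0) stop("Not an OpenDX gridpositions file: ", path,
                            call. = FALSE)
  counts <- as.integer(strsplit(sub(".*counts\\s+", "", cl[1]), "\\s+")[[1]])
  origin_line <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", origin_line)),
                                "\\s+")[[1]])
  delta_lines <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(delta_lines[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- c(deltas[1, 1], deltas[2, 2], deltas[3, 3])
  if (any(abs(deltas - diag(spacing)) > 1e-12 * max(abs(spacing)))) {
    stop("Only axis-aligned (diagonal delta) DX grids are supported",
         call. = FALSE)
  }
  data_start <- grep("data follows", lines)
  if (length(data_start) == 0) stop("No data section in DX file: ", path,
                                    call. = FALSE)
  items <- as.integer(sub(".*items\\s+(\\d+).*", "\\1", lines[data_start[1]]))
  body <- lines[(data_start[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", body)]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != items || items != prod(counts)) {
    stop("DX file '", path, "' declares ", items, " items over counts ",
         paste(counts, collapse = "x"), " but supplies ", length(vals),
         " values", call. = FALSE)
  }
  potential_grid(origin, spacing, counts, vals)
}
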