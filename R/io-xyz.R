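# Multi-frame XYZ I/O: repeated blocks of
#   n_atoms
#   comment
#   element x y z   (n_atoms lines)

#' Read an XYZ file
#'
#' Single- or multi-frame XYZ. With one frame a molecule tibble is returned
#' (serials 1..n, residue "MOL"); with several, a trajectory whose times are
#' taken from `time = <ps>` tokens in the comment lines when present, else the
#' frame index in ps.
#'
#' @param path Path to an `.xyz` file.
#' @param as_trajectory Force a trajectory return even for one frame.
#' @return A molecule tibble or a trajectory.
#' @export
read_xyz <- function(path, as_trajectory = FALSE) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  elements <- NULL
  times <- numeric(0)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("Malformed XYZ at line ", i, " of '", path,
                       "': expected atom count", call. = FALSE)
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    block <- lines[(i + 2L):(i + 1L + n)]
    f <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    if (ncol(f) < 4) stop("Malformed XYZ atom line near line ", i + 2L,
                          " of '", path, "'", call. = FALSE)
    el <- f[, 1]
    if (is.null(elements)) elements <- el
    xyz <- matrix(as.numeric(f[, 2:4]), ncol = 3)
    if (anyNA(xyz)) stop("Non-numeric coordinate near line ", i + 2L,
                         " of '", path, "'", call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    tm <- regmatches(comment, regexpr("time\\s*=\\s*[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm)) as.numeric(sub(".*=\\s*", "", tm))
               else length(frames))
    i <- i + 2L + n
  }
  topo <- tibble::tibble(
    serial = seq_along(elements), name = elements, element = elements,
    residue_name = "MOL", residue_id = 1L, chain = "A",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3]
  )
  if (length(frames) == 1L && !as_trajectory) return(as_molecule(topo))
  trajectory(topo, frames, times)
}

#' Write coordinates to XYZ
#'
#' @param x A molecule tibble, a trajectory, or a plain n x 3 matrix (then
#'   `elements` must be given).
#' @param path Output path.
#' @param elements Element symbols when `x` is a bare matrix.
#' @param comment Comment line (recycled per frame); frame times are appended
#'   as `time = <ps>` for trajectories.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, elements = NULL, comment = "flavotune") {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(el, xyz, cm) {
    writeLines(as.character(nrow(xyz)), con)
    writeLines(cm, con)
    writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  if (is_trajectory(x)) {
    for (k in seq_along(x$frames)) {
      emit(x$topology$element, x$frames[[k]],
           sprintf("%s time = %g", comment, x$times[k]))
    }
  } else if (is.data.frame(x)) {
    emit(x$element, coords_matrix(x), comment)
  } else {
    stopifnot(!is.null(elements))
    emit(elements, as.matrix(x), comment)
  }
  invisible(path)
}
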