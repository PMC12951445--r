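# broom-style tidiers for the result types.

#' Tidy an electrostatic projection map
#'
#' @param x An `epm_map`.
#' @param ... Unused.
#' @return A tibble of surface points with their projected values.
#' @exportS3Method generics::tidy
#' @export
tidy.epm_map <- function(x, ...) tibble::as_tibble(x)

#' Glance at an electrostatic projection map
#'
#' @param x An `epm_map`.
#' @param ... Unused.
#' @return One-row tibble: point count, value range and mean, clip range.
#' @exportS3Method generics::glance
#' @export
glance.epm_map <- function(x, ...) {
  clip <- attr(x, "color_clip")
  tibble::tibble(
    n_points = nrow(x), mean_value = mean(x$value),
    min_value = min(x$value), max_value = max(x$value),
    clip_low = clip[1], clip_high = clip[2],
    scale = attr(x, "scale") %||% NA_real_
  )
}

#' Tidy a spectral tuning map
#'
#' @param x An `estm_map`.
#' @param ... Unused.
#' @return A tibble of surface points with their shifts.
#' @exportS3Method generics::tidy
#' @export
tidy.estm_map <- function(x, ...) tibble::as_tibble(x)

#' Glance at a spectral tuning map
#'
#' @param x An `estm_map`.
#' @param ... Unused.
#' @return One-row tibble: state, probe, shift extrema.
#' @exportS3Method generics::glance
#' @export
glance.estm_map <- function(x, ...) {
  tibble::tibble(
    state = attr(x, "state"), probe = attr(x, "probe"),
    n_points = nrow(x),
    max_redshift = min(x$shift), max_blueshift = max(x$shift)
  )
}

#' Tidy a gap report
#'
#' @param x A `gap_report`.
#' @param ... Unused.
#' @return The per-region mean gap shifts as a tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.gap_report <- function(x, ...) x$region_gap_means

#' Glance at a gap report
#'
#' @param x A `gap_report`.
#' @param ... Unused.
#' @return One-row tibble with the extrema and combined capacity.
#' @exportS3Method generics::glance
#' @export
glance.gap_report <- function(x, ...) {
  tibble::tibble(
    max_redshift_S1 = x$max_redshift_S1,
    max_blueshift_Tn = x$max_blueshift_Tn,
    combined_capacity = x$combined_capacity,
    degenerate = x$degenerate
  )
}

#' Tidy an RMSF profile
#'
#' @param x An `rmsf_profile`.
#' @param ... Unused.
#' @return The profile as a plain tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.rmsf_profile <- function(x, ...) tibble::as_tibble(x)

#' Glance at an RMSF profile
#'
#' @param x An `rmsf_profile`.
#' @param ... Unused.
#' @return One-row tibble: residue count, mean/min/max RMSF, degeneracy.
#' @exportS3Method generics::glance
#' @export
glance.rmsf_profile <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x), mean_rmsf = mean(x$rmsf),
    min_rmsf = min(x$rmsf), max_rmsf = max(x$rmsf),
    degenerate = isTRUE(attr(x, "degenerate"))
  )
}
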