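# ggplot2 displays for the map and profile types. Maps are shown as a flat
# x/y scatter of surface points (the chromophore is planar, so the top-view
# projection is faithful); full 3D rendering is delegated to external
# programs via the pseudo-atom PDB exports.

#' Plot an electrostatic projection map
#'
#' Top-view scatter of the projection surface coloured by potential, clipped
#' to the map's display range (default -0.25..0.25 kT/e), red negative /
#' blue positive as is conventional for electrostatic surfaces.
#'
#' @param object An `epm_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.epm_map <- function(object, ...) {
  clip <- attr(object, "color_clip")
  if (is.null(clip)) clip <- c(-0.25, 0.25)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      shown = pmin(pmax(.data$value, clip[1]), clip[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$shown)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradient2(low = "red", mid = "white",
                                    high = "blue", midpoint = 0,
                                    limits = clip,
                                    name = "potential (kT/e)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "Electrostatic projection map") +
    ggplot2::theme_minimal()
}

#' Plot an electrostatic spectral tuning map
#'
#' Top-view scatter of the probe surface coloured by excitation-energy
#' shift: red where a positive probe red-shifts the state (stabilises it),
#' blue where it blue-shifts.
#'
#' @param object An `estm_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.estm_map <- function(object, ...) {
  lim <- max(abs(object$shift))
  if (lim == 0) lim <- 1e-6
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$shift)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradient2(low = "red", mid = "white",
                                    high = "blue", midpoint = 0,
                                    limits = c(-lim, lim),
                                    name = "shift (eV)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = paste0("Spectral tuning map: ",
                                 attr(object, "state"))) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' Line/point profile of RMSF by residue, with the mean as a dashed rule;
#' normalised values are shown when present.
#'
#' @param object An `rmsf_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  use_norm <- "normalized" %in% names(object)
  ycol <- if (use_norm) "normalized" else "rmsf"
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_id,
                                   y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = mean(df[[ycol]]), linetype = "dashed") +
    ggplot2::labs(x = "residue",
                  y = if (use_norm) "normalised RMSF" else "RMSF (Å)",
                  title = "Per-residue flexibility") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.epm_map
#' @param map An `epm_map`.
#' @export
plot_epm <- function(map, ...) autoplot.epm_map(map, ...)

#' @rdname autoplot.estm_map
#' @param map An `estm_map`.
#' @export
plot_estm <- function(map, ...) autoplot.estm_map(map, ...)
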