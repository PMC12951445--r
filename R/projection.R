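# Electrostatic projection maps (EPMs): sample a potential grid onto a
# chromophore surface cloud by averaging the nearest grid nodes.

# For each query point return the mean of the m nearest node values.
# The grid is regular, so the m nearest nodes lie inside a small index window
# around the point; the window is grown until it provably contains them
# (every excluded node is farther than the m-th candidate). Ties in distance
# are broken by lexicographic (ix, iy, iz) node index.
nearest_node_mean <- function(grid, pts, m) {
  n <- grid$counts
  sp <- grid$spacing
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    u <- (pts[p, ] - grid$origin) / sp       # fractional index, 0-based
    fl <- floor(u)
    w <- 2L
    repeat {
      rng <- lapply(1:3, function(a) {
        lo <- max(0L, as.integer(fl[a]) - w + 1L)
        hi <- min(n[a] - 1L, as.integer(fl[a]) + w)
        lo:hi
      })
      cand <- expand.grid(ix = rng[[1]], iy = rng[[2]], iz = rng[[3]])
      d2 <- (grid$origin[1] + cand$ix * sp[1] - pts[p, 1])^2 +
            (grid$origin[2] + cand$iy * sp[2] - pts[p, 2])^2 +
            (grid$origin[3] + cand$iz * sp[3] - pts[p, 3])^2
      if (nrow(cand) >= m) {
        ord <- order(d2, cand$ix, cand$iy, cand$iz)
        dmth <- sqrt(d2[ord[m]])
        # any node outside the window is at least (w-1) * min spacing away
        # along some axis from the point (which sits in cell fl..fl+1)
        window_guard <- (w - 1L) * min(sp)
        full <- all(vapply(1:3, function(a) {
          length(rng[[a]]) == n[a]
        }, logical(1)))
        if (dmth <= window_guard || full) {
          sel <- ord[seq_len(m)]
          out[p] <- mean(grid$values[cbind(cand$ix[sel] + 1L,
                                           cand$iy[sel] + 1L,
                                           cand$iz[sel] + 1L)])
          break
        }
      } else if (prod(n) < m) {
        stop("Grid has fewer nodes (", prod(n), ") than m_neighbors (", m,
             ")", call. = FALSE)
      }
      w <- w * 2L
    }
  }
  out
}

# Trilinear interpolation at query points (alternative to nearest-m mean).
trilinear_at <- function(grid, pts) {
  sp <- grid$spacing
  n <- grid$counts
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    u <- (pts[p, ] - grid$origin) / sp
    i0 <- pmin(pmax(floor(u), 0), n - 2)
    f <- u - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + wgt * grid$values[i0[1] + dx + 1, i0[2] + dy + 1,
                                     i0[3] + dz + 1]
    }
    out[p] <- acc
  }
  out
}

#' Project a potential grid onto a surface cloud
#'
#' The projected value at each surface point is the unweighted mean of the
#' `m_neighbors` nearest grid-node values under Euclidean distance (default
#' 8), with distance ties broken by lexicographic node index. This is the
#' stated projection rule of electrostatic projection maps; set
#' `method = "trilinear"` for conventional cell-corner interpolation instead.
#' Every surface point must lie inside the grid's bounding box.
#'
#' @param grid A [potential_grid()] (from [evaluate_grid()] or [read_dx()]).
#' @param cloud A surface cloud, ideally region-labelled via
#'   [assign_point_regions()].
#' @param m_neighbors Number of nearest nodes averaged (>= 1).
#' @param method `"nearest"` (mean of m nearest nodes) or `"trilinear"`.
#' @param color_clip Length-2 clip range in kT/e used by [export_colored()]
#'   and plots; the conventional display scale is c(-0.25, 0.25).
#' @return The cloud with a `value` column (kT/e) added; class `epm_map`.
#' @export
project <- function(grid, cloud, m_neighbors = 8,
                    method = c("nearest", "trilinear"),
                    color_clip = c(-0.25, 0.25)) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "potential_grid"), m_neighbors >= 1,
            length(color_clip) == 2, color_clip[1] < color_clip[2])
  pts <- as.matrix(cloud[, c("x", "y", "z")])
  hi <- grid$origin + (grid$counts - 1) * grid$spacing
  for (a in 1:3) {
    bad <- which(pts[, a] < grid$origin[a] - 1e-9 | pts[, a] > hi[a] + 1e-9)
    if (length(bad) > 0) {
      stop("Surface point ", bad[1], " at (",
           paste(signif(pts[bad[1], ], 6), collapse = ", "),
           ") lies outside the grid bounds [",
           paste(signif(grid$origin, 6), collapse = ", "), "] .. [",
           paste(signif(hi, 6), collapse = ", "), "]", call. = FALSE)
    }
  }
  vals <- if (method == "nearest") {
    nearest_node_mean(grid, pts, as.integer(m_neighbors))
  } else {
    trilinear_at(grid, pts)
  }
  out <- dplyr::mutate(cloud, value = vals)
  for (a in c("molecule", "scale", "density")) attr(out, a) <- attr(cloud, a)
  attr(out, "color_clip") <- as.numeric(color_clip)
  attr(out, "method") <- method
  class(out) <- c("epm_map", class(tibble::tibble()))
  out
}

#' Summarise a projection map by chromophore region
#'
#' Per-region mean/min/max/count of the projected potential, with a sign
#' verdict (`positive` iff min > 0, `negative` iff max < 0, else `mixed`).
#' Ring regions partition the cloud; the composite faces `N5/C4` and `C2/N3`
#' are added as extra rows.
#'
#' @param map An `epm_map` with region labels.
#' @return A tibble with columns `region`, `mean`, `min`, `max`, `n_points`,
#'   `sign`.
#' @export
summarize_regions <- function(map) {
  if (!"region" %in% names(map)) {
    stop("Projection map has no region labels; call assign_point_regions() ",
         "before project()", call. = FALSE)
  }
  one <- function(df, label) {
    tibble::tibble(
      region = label, mean = mean(df$value), min = min(df$value),
      max = max(df$value), n_points = nrow(df),
      sign = if (min(df$value) > 0) "positive"
             else if (max(df$value) < 0) "negative" else "mixed"
    )
  }
  rings <- dplyr::group_modify(dplyr::group_by(map, .data$region),
                               ~ one(.x, .y$region)[, -1]) |>
    dplyr::ungroup()
  rings <- dplyr::arrange(rings, .data$region)
  extra <- list()
  if (any(map$face_N5_C4)) {
    extra <- c(extra, list(one(map[map$face_N5_C4, ], "N5/C4")))
  }
  if (any(map$face_C2_N3)) {
    extra <- c(extra, list(one(map[map$face_C2_N3, ], "C2/N3")))
  }
  dplyr::bind_rows(rings, extra)
}

#' Export a projection map with display clipping
#'
#' Writes a CSV (`x, y, z, parent_serial, region, site, value,
#' clipped_value`) and optionally a pseudo-atom PDB carrying the clipped
#' value in the B-factor column. Values are clipped to the map's
#' `color_clip` range (default -0.25..0.25 kT/e, the conventional display
#' scale).
#'
#' @param map An `epm_map`.
#' @param csv CSV output path, or `NULL`.
#' @param pdb Pseudo-atom PDB output path, or `NULL`.
#' @return The map with a `clipped_value` column, invisibly.
#' @export
export_colored <- function(map, csv = NULL, pdb = NULL) {
  clip <- attr(map, "color_clip")
  if (is.null(clip)) clip <- c(-0.25, 0.25)
  out <- dplyr::mutate(map,
                       clipped_value = pmin(pmax(.data$value, clip[1]), clip[2]))
  if (!is.null(csv)) {
    cols <- intersect(c("x", "y", "z", "parent_serial", "region", "site",
                        "value", "clipped_value"), names(out))
    utils::write.csv(as.data.frame(out[, cols]), csv, row.names = FALSE)
  }
  if (!is.null(pdb)) {
    export_cloud(out, pdb = pdb, bfactor_column = "clipped_value")
  }
  invisible(out)
}
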