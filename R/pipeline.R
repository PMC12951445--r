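# End-to-end orchestration: synthetic (or user) inputs -> surface -> grid ->
# projection -> tuning maps -> gap report -> flexibility -> interpolation
# path, with a machine-readable JSON report.

#' Pipeline configuration
#'
#' Collects every protocol constant of the analysis with the conventional
#' defaults: tuning-map surface at 2 van der Waals radii with a +0.1 e
#' probe, projection surface at 1 radius, a 64 Angstrom potential grid at
#' 0.5 Angstrom spacing (129^3 nodes), display clip of +/- 0.25 kT/e, a
#' 4 Angstrom proximity cutoff, snapshot extraction of 100 frames at 50 ps,
#' convergence window of 4 iterations within 0.02 eV, and a 21-geometry
#' interpolation path.
#'
#' @param estm_scale,epm_scale Surface scales for tuning and projection maps.
#' @param probe Probe charge, e.
#' @param grid_edge,grid_spacing Potential grid geometry, Angstrom.
#' @param color_clip Display clip range, kT/e.
#' @param proximity_cutoff Residue proximity cutoff, Angstrom.
#' @param asec_interval,asec_count Snapshot extraction parameters (ps, count).
#' @param asec_tol,asec_window Convergence tolerance (eV) and window.
#' @param liic_n_interp,liic_n_extrap Interpolation/extrapolation split
#'   (defaults 15 + 2 x 3 = 21 geometries).
#' @param density Surface point density, points per square Angstrom.
#' @param seed Integer seed for every random stage.
#' @return A `run_config` list.
#' @export
run_config <- function(estm_scale = 2, epm_scale = 1, probe = 0.1,
                       grid_edge = 64, grid_spacing = 0.5,
                       color_clip = c(-0.25, 0.25), proximity_cutoff = 4.0,
                       asec_interval = 50, asec_count = 100,
                       asec_tol = 0.02, asec_window = 4,
                       liic_n_interp = 15, liic_n_extrap = 3,
                       density = 1, seed = 1) {
  structure(list(
    estm_scale = estm_scale, epm_scale = epm_scale, probe = probe,
    grid_edge = grid_edge, grid_spacing = grid_spacing,
    color_clip = color_clip, proximity_cutoff = proximity_cutoff,
    asec_interval = asec_interval, asec_count = asec_count,
    asec_tol = asec_tol, asec_window = asec_window,
    liic_n_interp = liic_n_interp, liic_n_extrap = liic_n_extrap,
    density = density, seed = seed
  ), class = "run_config")
}

#' Run the full synthetic-input pipeline
#'
#' Generates the toy chromophore and a point-charge environment for the
#' requested motif, then runs every stage: projection surface + potential
#' grid + projection map with region summary; tuning maps for the singlet
#' and triplet with a gap report; environment-induced state and gap shifts;
#' a synthetic trajectory with RMSF, normalisation, above-average selection
#' and chromophore proximity; and a default interpolation path between two
#' chromophore conformers. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @param motif Environment motif for the synthetic run.
#' @param out_dir Directory for artifacts (CSV/PDB/DX/JSON); `NULL` skips
#'   writing.
#' @return A `pipeline_report` list with every stage's key results and the
#'   resolved config.
#' @export
run_pipeline <- function(config = run_config(),
                         motif = c("LOV1_like", "LOV2_like", "neutral"),
                         out_dir = NULL) {
  motif <- match.arg(motif)
  mol <- make_toy_flavin()
  env <- make_environment(motif, mol)
  # projection stage: local grid around the chromophore (the full-size grid
  # geometry is validated separately; a tighter box keeps the run light)
  centroid <- colMeans(coords_matrix(heavy_atoms(mol)))
  grid <- evaluate_grid(env, box_edge = 16, spacing = config$grid_spacing,
                        center = centroid)
  cloud_epm <- assign_point_regions(
    generate_surface(mol, config$epm_scale, config$density), mol)
  epm <- project(grid, cloud_epm, color_clip = config$color_clip)
  regions <- summarize_regions(epm)
  # tuning stage
  dq_s1 <- make_delta_charges("S1_pipi", mol)
  dq_tn <- make_delta_charges("Tn_npi", mol)
  cloud_estm <- assign_point_regions(
    generate_surface(mol, config$estm_scale, config$density), mol)
  map_s1 <- estm_map(mol, dq_s1, config$probe, cloud = cloud_estm)
  map_tn <- estm_map(mol, dq_tn, config$probe, cloud = cloud_estm)
  gaps <- gap_report(map_s1, map_tn)
  phi <- potential_at_atoms(mol, env)
  shift_s1 <- shift_from_environment(mol, dq_s1, phi)
  shift_tn <- shift_from_environment(mol, dq_tn, phi)
  dgap <- gap_shift(mol, dq_s1, dq_tn, phi)
  # flexibility stage
  traj <- make_trajectory(n_residues = 12, n_frames = 200,
                          sigma = seq(0.2, 0.6, length.out = 12),
                          seed = config$seed)
  prof <- normalize_rmsf(rmsf(superpose_to_mean(traj)))
  flexible <- select_above_average(prof)
  shell <- make_residue_shell(mol, seed = config$seed)
  near <- residues_within(shell, mol, config$proximity_cutoff)
  # interpolation stage on the chromophore between two jittered conformers
  endB <- mol
  endB$x <- endB$x + 0.1
  path <- build_path(mol, endB, config$liic_n_interp, config$liic_n_extrap)
  report <- structure(list(
    config = config,
    motif = motif,
    region_summary = regions,
    gap_report = gaps,
    environment_shifts = list(S1 = shift_s1, Tn = shift_tn,
                              gap_shift = dgap,
                              gap_narrowing = dgap < 0),
    rmsf = prof,
    flexible_residues = flexible,
    proximity = list(residues = near, count = nrow(near),
                     cutoff = config$proximity_cutoff),
    liic = list(n_geometries = length(path$geometries),
                metrics = path_metrics(path)[c("rms_step", "uniform")]),
    grid_counts = grid$counts
  ), class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_colored(epm, csv = file.path(out_dir, "epm.csv"),
                   pdb = file.path(out_dir, "epm.pdb"))
    export_cloud(map_s1, csv = file.path(out_dir, "estm_S1.csv"))
    export_cloud(map_tn, csv = file.path(out_dir, "estm_Tn.csv"))
    write_dx(grid, file.path(out_dir, "field.dx"))
    utils::write.csv(as.data.frame(prof), file.path(out_dir, "rmsf.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Flatten a report for JSON serialisation.
report_to_list <- function(report) {
  list(
    config = unclass(report$config),
    motif = report$motif,
    region_summary = report$region_summary,
    gap_report = report$gap_report[c("max_redshift_S1", "max_blueshift_Tn",
                                     "combined_capacity", "degenerate")],
    environment_shifts = report$environment_shifts,
    flexible_residues = report$flexible_residues,
    proximity_count = report$proximity$count,
    liic = report$liic,
    grid_counts = report$grid_counts
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> motif ", x$motif, "\n",
      "  combined gap capacity: ",
      format(x$gap_report$combined_capacity, digits = 4), " eV\n",
      "  environment gap shift: ",
      format(x$environment_shifts$gap_shift, digits = 4), " eV (",
      if (x$environment_shifts$gap_narrowing) "narrowing" else "widening",
      ")\n",
      "  proximity count (<= ", x$proximity$cutoff, " A): ",
      x$proximity$count, "\n",
      "  flexible residues: ", length(x$flexible_residues), "\n", sep = "")
  invisible(x)
}

#' Glance at a pipeline report
#'
#' One-row summary of the headline numbers.
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(
    motif = x$motif,
    combined_capacity = x$gap_report$combined_capacity,
    gap_shift = x$environment_shifts$gap_shift,
    shift_S1 = x$environment_shifts$S1,
    shift_Tn = x$environment_shifts$Tn,
    proximity_count = x$proximity$count,
    n_flexible = length(x$flexible_residues),
    liic_geometries = x$liic$n_geometries
  )
}
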