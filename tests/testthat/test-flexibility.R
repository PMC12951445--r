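# Flexibility analysis: superposition, RMSF recovery, normalisation,
# selection, proximity, B-factor output.

test_that("rigid global motion is removed by superposition", {
  traj <- make_trajectory(n_residues = 8, n_frames = 20, sigma = 1e-12,
                          rigid_jitter = TRUE, seed = 4)
  prof <- rmsf(superpose_to_mean(traj))
  expect_true(all(prof$rmsf < 1e-6))
})

test_that("identical frames superpose to themselves with zero RMSF", {
  topo <- make_trajectory(n_residues = 6, n_frames = 1, sigma = 0.1,
                          seed = 5)$topology
  f <- as.matrix(topo[, c("x", "y", "z")])
  traj <- trajectory(topo, list(f, f, f), times = 1:3)
  aligned <- superpose_to_mean(traj)
  for (k in 1:3) expect_close(aligned$frames[[k]], f, 1e-9)
  expect_true(all(rmsf(aligned)$rmsf == 0))
})

test_that("prescribed sigma is recovered as sigma*sqrt(3) and jitter is benign", {
  # enough residues that the 6 rigid degrees of freedom absorbed by the
  # superposition are a negligible share of the fluctuation variance
  traj <- make_trajectory(n_residues = 100, n_frames = 4000, sigma = 0.3,
                          seed = 6)
  prof <- rmsf(superpose_to_mean(traj))
  expect_close(prof$rmsf / (0.3 * sqrt(3)), 1, 0.05)
  # with global rigid jitter, superposition recovers the same fluctuations
  trajj <- make_trajectory(n_residues = 100, n_frames = 4000, sigma = 0.3,
                           rigid_jitter = TRUE, seed = 6)
  profj <- rmsf(superpose_to_mean(trajj))
  # independent noise realisations: per-residue within sampling error,
  # profile mean much tighter
  expect_close(profj$rmsf / prof$rmsf, 1, 0.05)
  expect_close(mean(profj$rmsf) / mean(prof$rmsf), 1, 0.01)
})

test_that("RMSF ratios track prescribed sigma ratios", {
  # frames share one lab frame by construction, so no superposition needed
  traj <- make_trajectory(n_residues = 2, n_frames = 6000,
                          sigma = c(0.2, 0.6), seed = 7)
  prof <- rmsf(traj)
  expect_close(prof$rmsf[2] / prof$rmsf[1], 3, 0.15)
})

test_that("static trajectories give zero RMSF without superposition", {
  topo <- make_trajectory(n_residues = 5, n_frames = 1, sigma = 0.1,
                          seed = 8)$topology
  f <- as.matrix(topo[, c("x", "y", "z")])
  traj <- trajectory(topo, list(f, f), times = 1:2)
  expect_true(all(rmsf(traj)$rmsf == 0))
})

test_that("normalisation is the affine map with degenerate flagging", {
  prof <- tibble::tibble(residue_id = 1:3, rmsf = c(0.32, 0.82, 1.32))
  class(prof) <- c("rmsf_profile", class(tibble::tibble()))
  np <- normalize_rmsf(prof)
  expect_equal(np$normalized, c(0, 0.5, 1))
  expect_false(attr(np, "degenerate"))
  # already [0,1] profiles are unchanged
  np2 <- normalize_rmsf(tibble::tibble(residue_id = 1:3,
                                       rmsf = c(0, 0.5, 1)))
  expect_equal(np2$normalized, c(0, 0.5, 1))
  const <- normalize_rmsf(tibble::tibble(residue_id = 1:2,
                                         rmsf = c(0.5, 0.5)))
  expect_equal(const$normalized, c(0, 0))
  expect_true(attr(const, "degenerate"))
})

test_that("above-average selection is strict on normalised values", {
  prof <- normalize_rmsf(tibble::tibble(residue_id = 1:3,
                                        rmsf = c(0.0, 0.5, 1.0)))
  expect_equal(select_above_average(prof), 3L)  # mean 0.5, strict
  const <- normalize_rmsf(tibble::tibble(residue_id = 1:4, rmsf = rep(1, 4)))
  expect_length(select_above_average(const), 0)
  outlier <- normalize_rmsf(tibble::tibble(residue_id = 1:5,
                                           rmsf = c(1, 1, 1, 1, 2)))
  expect_equal(select_above_average(outlier), 5L)
})

test_that("proximity selection applies the inclusive heavy-atom cutoff", {
  chromo <- make_toy_flavin()
  far <- toy_molecule(c(50, 0, 0))
  expect_equal(nrow(residues_within(far, chromo)), 0)
  # one heavy atom exactly at 3.9 A from N5 along +z
  n5 <- as.numeric(chromo[which(chromo$site == "N5"), c("x", "y", "z")])
  near <- toy_molecule(c(n5[1], n5[2], n5[3] + 3.9))
  expect_equal(residues_within(near, chromo)$residue_id, 1L)
  # hydrogens never count
  h_only <- toy_molecule(c(n5[1], n5[2], n5[3] + 1.0), element = "H",
                         vdw = 1.2)
  expect_equal(nrow(residues_within(h_only, chromo)), 0)
  expect_error(residues_within(near, h_only), "no heavy atoms")
})

test_that("staggered-shell proximity counts match the brute-force oracle", {
  chromo <- make_toy_flavin()
  shell <- make_residue_shell(chromo, n_residues = 20, r_min = 2.5,
                              r_step = 0.5)
  for (cutoff in c(3, 4, 5, 8)) {
    got <- residues_within(shell, chromo, cutoff)
    # brute force over all heavy-atom pairs
    cc <- as.matrix(heavy_atoms(chromo)[, c("x", "y", "z")])
    want <- vapply(seq_len(nrow(shell)), function(i) {
      p <- as.numeric(shell[i, c("x", "y", "z")])
      any(sqrt(colSums((t(cc) - p)^2)) <= cutoff)
    }, logical(1))
    expect_equal(sort(got$residue_id), which(want))
  }
  # monotone in cutoff
  n3 <- nrow(residues_within(shell, chromo, 3))
  n4 <- nrow(residues_within(shell, chromo, 4))
  expect_gte(n4, n3)
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
  traj <- make_trajectory(n_residues = 5, n_frames = 200, sigma = 0.25,
                          seed = 9)
  ang <- 0.7
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  moved <- trajectory(traj$topology,
                      lapply(traj$frames, function(f) {
                        f %*% t(rot) + matrix(c(5, -3, 2), nrow(f), 3,
                                              byrow = TRUE)
                      }), traj$times)
  p1 <- rmsf(superpose_to_mean(traj))
  p2 <- rmsf(superpose_to_mean(moved))
  expect_close(p1$rmsf, p2$rmsf, 1e-6)
})

test_that("B-factor output carries per-residue values, missing as 0 with warning", {
  traj <- make_trajectory(n_residues = 4, n_frames = 50, sigma = 0.3,
                          seed = 10)
  prof <- normalize_rmsf(rmsf(superpose_to_mean(traj)))
  mol <- traj$topology
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(mol, prof, path)
  back <- read_pdb(path)
  expect_close(back$bfactor, round(prof$normalized, 2), 0.011)
  # residue absent from the profile
  expect_warning(write_bfactor_pdb(mol, prof[-2, ], path), "B = 0.00")
  back2 <- read_pdb(path)
  expect_equal(back2$bfactor[2], 0)
})

test_that("a combined multi-iteration trajectory carries all frames through", {
  # five 100-frame segments combined into one 500-frame analysis trajectory
  segs <- lapply(1:5, function(s) {
    make_trajectory(n_residues = 3, n_frames = 100, sigma = 0.2, dt = 50,
                    seed = s)
  })
  frames <- do.call(c, lapply(segs, `[[`, "frames"))
  times <- unlist(lapply(seq_along(segs), function(s) {
    segs[[s]]$times + (s - 1) * 5000
  }))
  combined <- trajectory(segs[[1]]$topology, frames, times)
  expect_length(combined, 500)
  prof <- rmsf(superpose_to_mean(combined))
  expect_equal(nrow(prof), 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(combined$topology, normalize_rmsf(prof), path)
  expect_true(file.exists(path))
})
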