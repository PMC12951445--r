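# Spectral tuning maps: closed forms, linearity/antisymmetry, the
# environment-shift estimators and the gap report.

test_that("difference charges must be finite, zero-sum and atom-matched", {
  expect_error(state_delta_charges("s", c(0.1, 0.05)), "sum to zero")
  dq <- state_delta_charges("s", c(0.1, -0.1))
  expect_equal(sum(dq$delta_q), 0)
  mol <- make_toy_flavin()
  expect_error(estm_map(mol, dq), "atoms")
  expect_error(estm_map(mol, make_delta_charges("S1_pipi", mol), probe = 0),
               "non-zero")
})

test_that("all-zero difference charges give an all-zero map", {
  mol <- make_toy_flavin()
  dq <- state_delta_charges("null", rep(0, nrow(mol)))
  mm <- estm_map(mol, dq)
  expect_true(all(mm$shift == 0))
})

test_that("single-atom map matches the closed-form pair interaction", {
  mol <- toy_molecule(c(0, 0, 0), vdw = 1.7)
  dq <- raw_delta(0.1)
  mm <- estm_map(mol, dq, probe = 0.1, scale = 2, density = 1)
  # every point at 3.4 A: shift = k_C^eV * 0.1 * 0.1 / 3.4
  expect_close(mm$shift, (332.0636 / 23.0605) * 0.01 / 3.4, 1e-9)
  expect_close(mm$shift, 0.04235, 1e-5)
})

test_that("maps are antisymmetric and exactly linear in probe and kernel", {
  mol <- make_toy_flavin()
  dq <- make_delta_charges("S1_pipi", mol)
  cloud <- assign_point_regions(generate_surface(mol, 2, 0.5), mol)
  base <- estm_map(mol, dq, probe = 0.1, cloud = cloud)
  neg <- estm_map(mol, dq, probe = -0.1, cloud = cloud)
  expect_close(neg$shift, -base$shift, 1e-9)
  triple <- estm_map(mol, dq, probe = 0.3, cloud = cloud)
  expect_close(triple$shift, 3 * base$shift, 1e-9)
  dq2 <- state_delta_charges("scaled", 0.5 * dq$delta_q)
  half <- estm_map(mol, dq2, probe = 0.1, cloud = cloud)
  expect_close(half$shift, 0.5 * base$shift, 1e-9)
})

test_that("uniform potential produces zero environment shift", {
  mol <- make_toy_flavin()
  dq <- make_delta_charges("S1_pipi", mol)
  expect_equal(shift_from_environment(mol, dq, rep(3.7, nrow(mol))), 0,
               tolerance = 1e-15)
})

test_that("a single-site potential term reproduces the hand product", {
  mol <- make_toy_flavin()
  dq_vec <- rep(0, nrow(mol))
  dq_vec[which(mol$site == "N5")] <- -0.05
  dq <- raw_delta(dq_vec)
  phi <- rep(0, nrow(mol))
  phi[which(mol$site == "N5")] <- 1
  got <- shift_from_environment(mol, dq, phi)
  expect_equal(got, -0.05 * (1.98720e-3 * 298.15 / 23.0605),
               tolerance = 1e-12)
  expect_equal(got, -0.001285, tolerance = 1e-3)
  expect_error(shift_from_environment(mol, dq, phi[-1]), "length")
})

test_that("tuning-map and environment-shift routes agree (same bilinear form)", {
  # environment = one point charge q at a surface position p: the
  # environment-shift estimator must equal (q / probe) * map shift at p
  mol <- make_toy_flavin()
  dq <- make_delta_charges("Tn_npi", mol)
  cloud <- generate_surface(mol, 2, 0.3)
  mm <- estm_map(mol, dq, probe = 0.1, cloud = cloud)
  set.seed(9)
  for (i in sample.int(nrow(cloud), 5)) {
    q <- 0.37
    env <- charge_set(matrix(as.numeric(cloud[i, c("x", "y", "z")]),
                             ncol = 3), q)
    phi <- potential_at_atoms(mol, env)
    expect_equal(shift_from_environment(mol, dq, phi),
                 (q / 0.1) * mm$shift[i], tolerance = 1e-9)
  }
})

test_that("packaged kernels give the LOV1/LOV2 sign structure below N5/C4", {
  mol <- make_toy_flavin()
  dq_s1 <- make_delta_charges("S1_pipi", mol)
  dq_tn <- make_delta_charges("Tn_npi", mol)
  n5 <- as.numeric(mol[which(mol$site == "N5"), c("x", "y", "z")])
  below <- matrix(n5 - c(0, 0, 3), ncol = 3)
  # a positive point charge 3 A beneath N5
  phi <- potential_at_atoms(mol, charge_set(below, 0.5))
  s1 <- shift_from_environment(mol, dq_s1, phi)
  tn <- shift_from_environment(mol, dq_tn, phi)
  expect_lt(s1, 0)   # singlet red-shifts
  expect_gt(tn, 0)   # triplet blue-shifts
  dgap <- gap_shift(mol, dq_s1, dq_tn, phi)
  expect_equal(dgap, tn - s1, tolerance = 1e-12)
  expect_gt(dgap, 0)
  # brute-force sum oracle for the gap
  pos <- as.matrix(mol[, c("x", "y", "z")])
  d <- sqrt(colSums((t(pos) - as.numeric(below))^2))
  kt_ev <- 1.98720e-3 * 298.15 / 23.0605
  pref <- 332.0636 / (1.98720e-3 * 298.15)
  brute <- sum(pref * 0.5 / d * (dq_tn$delta_q - dq_s1$delta_q)) * kt_ev
  expect_equal(dgap, brute, tolerance = 1e-9)
  # negative charge narrows the gap (antisymmetry)
  expect_equal(gap_shift(mol, dq_s1, dq_tn, -phi), -dgap, tolerance = 1e-12)
  # probe-map sign audit on the surface points nearest the face underside
  cloud <- assign_point_regions(generate_surface(mol, 2, 1), mol)
  mm_s1 <- estm_map(mol, dq_s1, cloud = cloud)
  mm_tn <- estm_map(mol, dq_tn, cloud = cloud)
  under <- cloud$face_N5_C4 & cloud$z < -1
  expect_true(all(mm_s1$shift[under] < 0))
  expect_true(all(mm_tn$shift[under] > 0))
})

test_that("gap report combines the extrema and scans match brute force", {
  mol <- make_toy_flavin()
  cloud <- assign_point_regions(generate_surface(mol, 2, 0.5), mol)
  mm_s1 <- estm_map(mol, make_delta_charges("S1_pipi", mol), cloud = cloud)
  mm_tn <- estm_map(mol, make_delta_charges("Tn_npi", mol), cloud = cloud)
  rep <- gap_report(mm_s1, mm_tn)
  expect_equal(rep$combined_capacity,
               abs(min(mm_s1$shift)) + max(mm_tn$shift), tolerance = 1e-12)
  expect_false(rep$degenerate)
  expect_equal(abs(rep$max_redshift_S1) + rep$max_blueshift_Tn,
               rep$combined_capacity)
  # random kernel: capacity equals the exhaustive scan
  set.seed(14)
  v <- rnorm(nrow(mol)); v <- v - mean(v)
  w <- rnorm(nrow(mol)); w <- w - mean(w)
  ma <- estm_map(mol, state_delta_charges("a", v), cloud = cloud)
  mb <- estm_map(mol, state_delta_charges("b", w), cloud = cloud)
  rep2 <- gap_report(ma, mb)
  expect_equal(rep2$combined_capacity,
               abs(min(0, min(ma$shift))) + max(0, max(mb$shift)),
               tolerance = 1e-12)
})

test_that("degenerate all-zero map pairs are flagged with zero capacity", {
  mol <- make_toy_flavin()
  cloud <- generate_surface(mol, 2, 0.3)
  zero <- state_delta_charges("z", rep(0, nrow(mol)))
  mz <- estm_map(mol, zero, cloud = cloud)
  rep <- gap_report(mz, mz)
  expect_equal(rep$combined_capacity, 0)
  expect_true(rep$degenerate)
  # mismatched clouds error
  other <- estm_map(mol, zero, cloud = generate_surface(mol, 1, 0.3))
  expect_error(gap_report(mz, other), "share one surface cloud")
})

test_that("delta-charge files round-trip by atom serial", {
  mol <- make_toy_flavin()
  dq <- make_delta_charges("S1_pipi", mol)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %.10f", rev(mol$serial), rev(dq$delta_q)), path)
  back <- read_delta_charges(path, mol, state = "S1_pipi")
  expect_close(back$delta_q, dq$delta_q, 1e-9)
})
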