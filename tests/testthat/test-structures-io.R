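# Format I/O: PDB, PQR, DX, XYZ round trips and the radius table.

test_that("PDB reader preserves atoms, serials and order", {
  path <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  mol <- read_pdb(path)
  expect_equal(nrow(mol), 3)
  expect_equal(mol$serial, 1:3)
  expect_equal(mol$element, c("N", "C", "C"))
  expect_equal(mol$residue_id, c(1L, 1L, 2L))
  expect_equal(mol$x, c(11.104, 12.560, 13.000))
  expect_false("charge" %in% names(mol) && !anyNA(mol$charge))
})

test_that("multi-model PDB yields a trajectory with one frame per model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  block <- readLines(write_tiny_pdb(withr::local_tempfile(fileext = ".pdb")))
  block <- block[block != "END"]
  writeLines(c("MODEL        1", block, "ENDMDL",
               "MODEL        2", sub("11.104", "12.104", block), "ENDMDL",
               "END"), path)
  traj <- read_pdb(path, multi_model = TRUE)
  expect_s3_class(traj, "flavotune_trajectory")
  expect_length(traj, 2)
  expect_equal(nrow(traj$topology), 3)
  expect_equal(traj$frames[[2]][1, 1], 12.104)
})

test_that("hybrid-36 residue ids beyond 9999 are decoded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # resSeq "A000" encodes 10000; "A009" encodes 10009
  lines <- c(
    "ATOM      1  CA  ALA AA000      1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA AA009      2.000   2.000   3.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  mol <- read_pdb(path)
  expect_equal(mol$residue_id, c(10000L, 10009L))
})

test_that("malformed PDB coordinates raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      xxxxx   2.000   3.000  1.00  0.00           C"),
    path)
  expect_error(read_pdb(path), "line 2")
})

test_that("PQR fields map to charge and radius and total charge sums", {
  path <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 N ALA A 1 0.0 0.0 0.0 -0.5 1.7", path)
  mol <- read_pqr(path)
  expect_equal(mol$charge, -0.5)
  expect_equal(mol$vdw_radius, 1.7)
  expect_equal(mol$chain, "A")

  # 10 atoms with charges summing to -2
  q <- c(-0.6, -0.4, 0.3, -0.5, 0.2, -0.3, -0.4, 0.1, -0.2, -0.2)
  lines <- sprintf("ATOM %d C UNK 1 %f 0.0 0.0 %f 1.7", 1:10,
                   as.numeric(1:10), q)
  writeLines(lines, path)
  mol <- read_pqr(path)
  expect_equal(total_charge(mol), -2, tolerance = 1e-9)
  # permutation invariance of the total
  expect_equal(total_charge(mol[sample.int(10), ]), total_charge(mol))
})

test_that("PQR write/read round trip preserves all fields to 1e-6", {
  mol <- toy_molecule(matrix(rnorm(15), ncol = 3), charge = 0.123456,
                      residue_id = c(1L, 1L, 2L, 2L, 3L))
  mol$charge <- c(-0.5, 0.25, 0.125, -0.3, 0.425)
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(mol, path)
  back <- read_pqr(path)
  expect_equal(back$serial, mol$serial)
  for (col in c("x", "y", "z", "charge", "vdw_radius")) {
    expect_close(back[[col]], mol[[col]], 1e-6)
  }
  expect_error(read_pqr({
    writeLines("ATOM 1 N ALA 1 0.0 0.0 0.0 -0.5", path); path
  }), "charge/radius|fields")
})

test_that("DX grids round-trip and report header counts", {
  g <- potential_grid(c(0, 0, 0), 0.5, c(2, 2, 2), rep(0, 8))
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  back <- read_dx(path)
  expect_equal(back$counts, g$counts)
  expect_identical(back$values, g$values)

  vals <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  g2 <- potential_grid(c(-1, 2, 0.5), c(0.5, 0.25, 1), c(3, 4, 5), vals)
  write_dx(g2, path)
  back2 <- read_dx(path)
  expect_close(back2$values, g2$values, 1e-6)
  expect_close(back2$origin, g2$origin, 1e-9)
  expect_close(back2$spacing, g2$spacing, 1e-9)
  # header counts line as solvers print it
  hdr <- grep("gridpositions", readLines(path), value = TRUE)[1]
  expect_match(hdr, "counts 3 4 5")
})

test_that("external-dialect DX fixture parses with matching geometry", {
  path <- test_path("fixtures", "pb_solver_synthetic.dx")
  g <- read_dx(path)
  expect_equal(g$counts, c(3L, 3L, 3L))
  expect_close(g$origin, c(-1, -1, -1), 1e-9)
  expect_close(g$spacing, c(1, 1, 1), 1e-9)
  # z-fastest ordering: value at [1,1,3] is the third stored number
  expect_equal(g$values[1, 1, 3], 0.02)
})

test_that("grid value-count mismatches are format errors", {
  path <- withr::local_tempfile(fileext = ".dx")
  g <- potential_grid(c(0, 0, 0), 1, c(2, 2, 2), rep(1, 8))
  write_dx(g, path)
  lines <- readLines(path)
  writeLines(lines[-(grep("data follows", lines) + 1)], path)
  expect_error(read_dx(path), "supplies")
  expect_error(potential_grid(c(0, 0, 0), 1, c(2, 2, 2), rep(1, 7)),
               "Expected 8")
})

test_that("XYZ multi-frame round trip preserves coordinates and times", {
  traj <- make_trajectory(n_residues = 4, n_frames = 3, sigma = 0.2,
                          dt = 10, seed = 7)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, path)
  back <- read_xyz(path)
  expect_length(back, 3)
  expect_equal(back$times, c(10, 20, 30))
  for (k in 1:3) expect_close(back$frames[[k]], traj$frames[[k]], 1e-6)
})

test_that("written PDB agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  mol <- make_toy_flavin()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(mol, path, bfactor = seq(0, 1.6, by = 0.1))
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ref$atom), nrow(mol))
  expect_close(ref$atom$x, mol$x, 1e-3)
  expect_close(ref$atom$y, mol$y, 1e-3)
  expect_close(ref$atom$b, seq(0, 1.6, by = 0.1), 1e-9)
  expect_equal(ref$atom$resid, mol$residue_name)
  # and our reader agrees with bio3d on the same file
  back <- read_pdb(path)
  expect_close(back$x, ref$atom$x, 1e-9)
  expect_equal(back$serial, ref$atom$eleno)
})

test_that("radius lookup uses the table, supports override and rejects unknowns", {
  expect_equal(vdw_radius("C"), 1.70)
  expect_equal(vdw_radius("c"), 1.70)
  expect_equal(vdw_radius("N", table = c(N = 1.6)), 1.6)
  expect_error(vdw_radius("Xx"), "Unknown element")
  tab_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# custom radii", "C 1.9", "N 1.6"), tab_path)
  tab <- read_radius_table(tab_path)
  expect_equal(vdw_radius("C", table = tab), 1.9)
})
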