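# Shared fixtures, all built in code.

# Minimal molecule: n atoms at given coordinates, all carbon unless stated.
toy_molecule <- function(coords, element = "C", vdw = 1.7,
                         residue_id = NULL, charge = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  m <- tibble::tibble(
    serial = seq_len(n), name = rep_len(element, n),
    element = rep_len(element, n),
    residue_name = "UNK",
    residue_id = if (is.null(residue_id)) rep(1L, n) else residue_id,
    chain = "A",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    vdw_radius = rep_len(vdw, n)
  )
  if (!is.null(charge)) m$charge <- rep_len(charge, n)
  as_molecule(m)
}

# Unchecked difference-charge kernel (single-pair examples need not conserve
# charge).
raw_delta <- function(delta_q, state = "test") {
  structure(list(state = state, delta_q = delta_q),
            class = "state_delta_charges")
}

# Hand-written 3-atom PDB fixture.
write_tiny_pdb <- function(path, resid = c(1L, 1L, 2L)) {
  lines <- c(
    sprintf("ATOM  %5d  N   ALA A%4d      11.104  13.207   2.100  1.00  0.50           N", 1L, resid[1]),
    sprintf("ATOM  %5d  CA  ALA A%4d      12.560  13.300   2.300  1.00  0.75           C", 2L, resid[2]),
    sprintf("ATOM  %5d  C   GLY A%4d      13.000  14.700   2.750  1.00  1.00           C", 3L, resid[3]),
    "END")
  writeLines(lines, path)
  path
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = paste0("max deviation ",
                             format(max(abs(actual - expected)))))
}
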