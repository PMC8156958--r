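# Structure / trajectory loading, selections and superposition.

test_that("a minimal PDB record parses to one atom at the printed coordinates", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00           C",
    "END"), p)
  s <- load_structure(p)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$x, s$y, s$z), c(11.104, 13.207, 2.100))
  expect_equal(s$resname, "ALA")
  expect_equal(s$element, "C")
})

test_that("fixture-text structures round-trip and residue keys are counted", {
  s <- make_structure(resno = c(5L, 5L, 9L, 9L), resname = c("ALA", "ALA", "GLY", "GLY"),
                      x = round(runif(4, 0, 30), 6), y = round(runif(4, 0, 30), 6),
                      z = round(runif(4, 0, 30), 6))
  p <- withr::local_tempfile(fileext = ".txt")
  write_structure_text(s, p)
  s2 <- load_structure(p, format = "txt")
  expect_identical(s2$x, s$x)   # bit-identical round trip at 6 dp inputs
  expect_identical(s2$y, s$y)
  expect_identical(s2$z, s$z)
  expect_equal(length(unique(paste(s2$chain, s2$resno))), 2L)
})

test_that("invalid structures are rejected", {
  tb <- tibble::tibble(atom_id = c(1L, 1L), name = "CA", element = "C",
                       chain = "A", resno = c(1L, 2L), resname = "ALA",
                       x = 0, y = 0, z = 0)
  expect_error(as_structure(tb), "duplicated atom_id")
  tb2 <- tb; tb2$atom_id <- 1:2; tb2$element <- c("C", "")
  expect_error(as_structure(tb2), "element")
  tb3 <- tb; tb3$atom_id <- 1:2; tb3$resno <- c(1L, 1L)
  tb3$resname <- c("ALA", "GLY")
  expect_error(as_structure(tb3), "conflicting residue names")
})

test_that("ligand discovery follows the OXY/NO dialect", {
  s <- make_structure(resno = c(10L, 701L, 701L, 805L, 805L),
                      resname = c("ALA", "OXY", "OXY", "NO", "NO"),
                      x = 1:5, y = 1:5, z = 1:5,
                      element = c("C", "O", "O", "N", "O"))
  ligs <- find_ligands(s)
  expect_equal(ligs$label, c("OXY_701", "NO_805"))
  expect_equal(ligs$species, c("O2", "NO"))
  # no gas residues -> empty
  expect_equal(nrow(find_ligands(make_structure(1L, "ALA", 0, 0, 0))), 0L)
  # wrong atom count for the species -> error
  s3 <- make_structure(resno = c(701L, 701L, 701L), resname = "OXY",
                       x = 1:3, y = 1:3, z = 1:3, element = "O")
  expect_error(find_ligands(s3), "expects 2")
})

test_that("residue shells use inclusive radii and match brute force", {
  # residues at 5 / 19.9 / 20.1 Angstrom from the centre atom
  s <- make_structure(resno = c(1L, 2L, 3L, 4L), resname = c("FE", "R1", "R2", "R3"),
                      x = c(0, 5, 19.9, 20.1), y = 0, z = 0,
                      element = c("Fe", "C", "C", "C"))
  keys <- residues_within(s, center_atom_id = 1L, radius = 20)
  expect_setequal(keys, c("A:1:FE", "A:2:R1", "A:3:R2"))

  for (seed in 1:5) {
    fx <- random_fixture(n_res = 120, seed = seed)  # ~500 atoms with 2/res
    got <- residues_within(fx, center_atom_id = 1L, radius = 12)
    want <- bf_residues_within(fx, as.matrix(fx[, c("x", "y", "z")]), 1L, 12)
    expect_setequal(got, want)
  }
})

test_that("trajectory loading checks shapes and carries time", {
  s <- make_structure(resno = c(1L, 1L), resname = "ALA", x = c(0, 1),
                      y = 0, z = 0)
  co <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  tr <- as_trajectory(s, co, 0.1)
  expect_equal(n_frames(tr), 2L)
  expect_equal(frame_times(tr), c(0, 0.1))
  # 1500 frames at 0.1 ns/frame covers 150 ns
  tr2 <- as_trajectory(s, array(0, c(1500, 2, 3)), 0.1)
  expect_equal(run_length(tr2), 150)
  expect_error(as_trajectory(s, array(0, c(2, 3, 3)), 0.1), "mismatch")
  expect_error(as_trajectory(s, array(0, c(0, 2, 3)), 0.1), "at least one frame")
  expect_error(as_trajectory(s, co, 0), "frame_interval")
})

test_that("fixture-text trajectories round-trip bit-identically", {
  s <- make_structure(resno = c(1L, 1L, 2L), resname = c("ALA", "ALA", "GLY"),
                      x = 1:3, y = 1:3, z = 1:3)
  co <- array(round(runif(4 * 3 * 3, 0, 50), 6), c(4, 3, 3))
  tr <- as_trajectory(s, co, 0.25)
  p <- withr::local_tempfile(fileext = ".txt")
  write_trajectory_text(tr, p)
  tr2 <- load_trajectory(p, s)
  expect_identical(tr2$coords, tr$coords)
  expect_equal(tr2$frame_interval, 0.25)
  # atom-count mismatch is rejected
  s4 <- make_structure(resno = 1L, resname = "ALA", x = 0, y = 0, z = 0)
  expect_error(load_trajectory(p, s4), "mismatch")
})

test_that("DCD round trip preserves coordinates to single precision", {
  s <- make_structure(resno = c(1L, 1L), resname = "ALA", x = c(0, 1),
                      y = 0, z = 0)
  co <- array(runif(5 * 2 * 3, 0, 60), c(5, 2, 3))
  tr <- as_trajectory(s, co, 0.1)
  p <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory_dcd(tr, p)
  tr2 <- load_trajectory(p, s, frame_interval = 0.1)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-5)
})

test_that("distances are invariant under rigid transforms of a frame", {
  fx <- random_fixture(n_res = 40, seed = 11)
  fr <- as.matrix(fx[, c("x", "y", "z")])
  lig <- lig_row(fx)
  res <- unique(paste(fx$chain, fx$resno, fx$resname, sep = ":"))[1:10]
  base <- contact_matrix(fx, fr, lig, res, cutoff = 8)
  for (seed in 1:5) {
    fr2 <- random_rigid(fr, seed)
    expect_identical(contact_matrix(fx, fr2, lig, res, cutoff = 8), base)
  }
})

test_that("region displacement recovers planted rigid motions", {
  set.seed(3)
  n <- 30L
  s <- make_structure(resno = rep(1:10, each = 3), resname = "ALA",
                      x = runif(n, 0, 20), y = runif(n, 0, 20),
                      z = runif(n, 0, 20))
  ref_keys <- paste0("A:", 1:5, ":ALA")
  reg_keys <- paste0("A:", 6:10, ":ALA")
  # identical inputs: zero everywhere
  d0 <- region_displacement(s, s, reg_keys, ref_keys)
  expect_true(all(abs(d0$displacement) < 1e-10))
  expect_lt(attr(d0, "reference_rmsd"), 1e-10)
  # region translated by 4 Angstrom, reference untouched
  s2 <- s
  reg_rows <- s$resno >= 6
  s2$x[reg_rows] <- s$x[reg_rows] + 4
  d4 <- region_displacement(s, s2, reg_keys, ref_keys)
  expect_equal(d4$displacement, rep(4, 5), tolerance = 1e-10)
  expect_lt(attr(d4, "reference_rmsd"), 1e-10)
  # global rotation+translation: all displacements vanish after superposition
  M <- random_rigid(as.matrix(s[, c("x", "y", "z")]), seed = 7)
  s3 <- s; s3$x <- M[, 1]; s3$y <- M[, 2]; s3$z <- M[, 3]
  d3 <- region_displacement(s, s3, reg_keys, ref_keys)
  expect_true(all(abs(d3$displacement) < 1e-8))
  # collinear reference is rejected
  s_col <- make_structure(resno = rep(1:2, each = 3), resname = "ALA",
                          x = c(1:3, 4:6), y = 0, z = 0)
  expect_error(region_displacement(s_col, s_col, "A:2:ALA", "A:1:ALA"),
               "collinear")
})
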