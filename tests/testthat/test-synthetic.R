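# Synthetic generator: model geometry, determinism, plant fidelity, bundles.

test_that("the bead model resolves all named sites with separated centroids", {
  m <- build_protein_model()
  expect_setequal(m$catalog$site, c("E1", "S1", "CAT", "S2", "E3"))
  for (i in seq_len(nrow(m$catalog))) {
    rows <- residue_atom_rows(m$structure, m$catalog$residues[[i]])
    expect_equal(length(rows), length(m$catalog$residues[[i]]))
  }
  cm <- do.call(rbind, m$centroids)
  dd <- as.matrix(dist(cm))
  expect_true(all(dd[upper.tri(dd)] >= 8))   # pairwise centroid separation
  # degenerate geometry is rejected
  expect_error(build_protein_model(pocket_radius = 0), "positive")
  expect_error(build_protein_model(box = c(8, 8, 8)), "degenerate|overlap")
})

test_that("identical spec and seed give bit-identical trajectories and bundles", {
  sp <- synthetic_spec(seed = 77, run_length = 5, frame_interval = 0.1,
                       n_o2 = 2, n_no = 2,
                       plants = list(plant_dwell("OXY_701", "S1", 1, 2)))
  s1 <- simulate_gas_trajectory(sp)
  s2 <- simulate_gas_trajectory(sp)
  expect_identical(s1$traj$coords, s2$traj$coords)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(s1, d1); write_fixture_bundle(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the gas coordinates
  s3 <- simulate_gas_trajectory(synthetic_spec(seed = 78, run_length = 5,
                                               frame_interval = 0.1,
                                               n_o2 = 2, n_no = 2))
  expect_false(identical(s1$traj$coords, s3$traj$coords))
})

test_that("ratio presets give the stated species counts", {
  s11 <- synthetic_spec(seed = 1, ratio = "1:1")
  expect_equal(c(s11$n_o2, s11$n_no), c(5, 5))
  s13 <- synthetic_spec(seed = 1, ratio = "1:3")
  expect_equal(c(s13$n_o2, s13$n_no), c(5, 15))
  s31 <- synthetic_spec(seed = 1, ratio = "3:1")
  expect_equal(c(s31$n_o2, s31$n_no), c(15, 5))
  synth <- simulate_gas_trajectory(synthetic_spec(seed = 2, run_length = 1,
                                                  frame_interval = 0.1,
                                                  ratio = "1:1"))
  lig <- find_ligands(synth$traj$structure)
  expect_equal(sum(lig$species == "O2"), 5L)
  expect_equal(sum(lig$species == "NO"), 5L)
})

test_that("planted dwells are recovered exactly by the contact pipeline", {
  synth <- simulate_gas_trajectory(synthetic_spec(
    seed = 13, run_length = 100, frame_interval = 0.1, n_o2 = 1, n_no = 1,
    plants = list(plant_dwell("OXY_701", "S1", 10, 70),
                  plant_dwell("NO_801", "S2", 5, 35))))
  lig <- find_ligands(synth$traj$structure)
  for (lb in c("OXY_701", "NO_801")) {
    planted <- synth$truth$dwells[synth$truth$dwells$ligand == lb, ]
    tr <- trace_path(synth$traj, lig[lig$label == lb, ], synth$catalog)
    expect_equal(nrow(tr), nrow(planted))
    expect_equal(tr$site, planted$site)
    expect_lte(max(abs(tr$start_frame - planted$start_frame)), 1L)
    expect_lte(max(abs(tr$end_frame - planted$end_frame)), 1L)
  }
  # the planted 70 ns dwell is recovered at full duration
  s1 <- synth$truth$dwells[synth$truth$dwells$site == "S1", ]
  expect_equal(s1$duration, 70)
})

test_that("infeasible plant scripts are rejected", {
  expect_error(simulate_gas_trajectory(synthetic_spec(
    seed = 1, run_length = 20, frame_interval = 0.1, n_o2 = 1, n_no = 0,
    plants = list(plant_dwell("OXY_701", "S1", 2, 10),
                  plant_dwell("OXY_701", "S2", 5, 10)))),
    "overlapping")
  expect_error(simulate_gas_trajectory(synthetic_spec(
    seed = 1, run_length = 20, frame_interval = 0.1, n_o2 = 1, n_no = 0,
    plants = list(plant_dwell("OXY_701", "S1", 2, 30)))),
    "outside the run")
  expect_error(simulate_gas_trajectory(synthetic_spec(
    seed = 1, run_length = 20, frame_interval = 0.1, n_o2 = 1, n_no = 0,
    plants = list(plant_dwell("OXY_999", "S1", 2, 5)))),
    "unknown ligand")
  expect_error(synthetic_spec(seed = 1, run_length = 10,
                              frame_interval = 0.3), "integer number")
})

test_that("bundles round-trip through the loaders with consistent truth", {
  synth <- simulate_gas_trajectory(synthetic_spec(
    seed = 21, run_length = 10, frame_interval = 0.1, n_o2 = 2, n_no = 1,
    plants = list(plant_dwell("OXY_701", "S1", 2, 3),
                  plant_dwell("NO_801", "E3", 5, 2))))
  d <- withr::local_tempdir()
  files <- write_fixture_bundle(synth, d)
  s2 <- load_structure(files$structure_txt, format = "txt")
  t2 <- load_trajectory(files$trajectory_txt, s2)
  expect_equal(dim(t2$coords), dim(synth$traj$coords))
  expect_equal(t2$coords, synth$traj$coords, tolerance = 1e-6)
  spdb <- load_structure(files$structure_pdb)
  expect_equal(nrow(spdb), nrow(synth$traj$structure))
  expect_equal(spdb$resname, synth$traj$structure$resname)
  truth <- read_ground_truth(d)
  expect_equal(nrow(truth$dwells), nrow(synth$truth$dwells))
  expect_equal(nrow(truth$displacements), 0L)
  cat2 <- read_site_catalog(files$sites)
  expect_setequal(cat2$site, synth$catalog$site)
  refs2 <- read_reference_atoms(files$refs)
  expect_equal(refs2$fe, synth$refs$fe)
  expect_equal(refs2$c15, synth$refs$c15)
})

test_that("periodic variants carry the box through to distance computations", {
  synth <- simulate_gas_trajectory(synthetic_spec(
    seed = 3, run_length = 2, frame_interval = 0.1, n_o2 = 1, n_no = 0,
    periodic = TRUE))
  expect_equal(synth$traj$box, c(60, 60, 60))
  # minimum image: two points 58 apart along x are 2 apart in a 60 box
  s <- make_structure(resno = c(1L, 2L), resname = c("R1", "R2"),
                      x = c(1, 59), y = 0, z = 0)
  keys <- residues_within(s, center_atom_id = 1L, radius = 5,
                          box = c(60, 60, 60))
  expect_true("A:2:R2" %in% keys)
  keys2 <- residues_within(s, center_atom_id = 1L, radius = 5)
  expect_false("A:2:R2" %in% keys2)
})
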