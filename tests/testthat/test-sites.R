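# Site occupancy intervals, qualification, path tracing, entrance calls.

# build a timeline tibble directly: one ligand, given per-residue contact
mk_timeline <- function(contacts_by_res, dt = 0.1, ligand = "OXY_701") {
  dplyr::bind_rows(lapply(names(contacts_by_res), function(r) {
    v <- contacts_by_res[[r]]
    tibble::tibble(ligand = ligand, residue = r,
                   frame = seq_along(v) - 1L,
                   time = (seq_along(v) - 1L) * dt,
                   min_distance = ifelse(v, 1, 10), contact = v)
  }))
}

test_that("occupancy intervals recover planted contiguous dwells", {
  nf <- 1000L
  v <- logical(nf); v[101:800] <- TRUE   # frames 100-799: 700 frames
  tl <- mk_timeline(list("A:413:ASN" = v))
  iv <- site_occupancy(tl, "S1", frame_interval = 0.1, merge_gap = 0)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start_frame, 100L)
  expect_equal(iv$end_frame, 799L)
  expect_equal(iv$duration, 70)          # the S1-scale dwell
  # no contact anywhere -> empty
  expect_equal(nrow(site_occupancy(mk_timeline(list("A:413:ASN" = logical(50))),
                                   "S1", 0.1)), 0L)
})

test_that("gap merging joins runs separated by short gaps only", {
  v <- logical(100)
  v[11:30] <- TRUE; v[34:50] <- TRUE    # 0.3 ns gap (frames 31-33)
  v[71:90] <- TRUE                      # 2.0 ns gap before this run
  tl <- mk_timeline(list("A:1:X" = v))
  iv <- site_occupancy(tl, "S", 0.1, merge_gap = 0.5)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start_frame, c(10L, 70L))
  expect_equal(iv$end_frame, c(49L, 89L))
  # with merging disabled the three runs stay distinct
  iv0 <- site_occupancy(tl, "S", 0.1, merge_gap = 0)
  expect_equal(nrow(iv0), 3L)
})

test_that("raising min_residues never lengthens occupancy", {
  set.seed(5)
  v1 <- runif(300) < 0.4; v2 <- runif(300) < 0.4
  tl <- mk_timeline(list("A:1:X" = v1, "A:2:X" = v2))
  iv1 <- site_occupancy(tl, "S", 0.1, min_residues = 1, merge_gap = 0)
  iv2 <- site_occupancy(tl, "S", 0.1, min_residues = 2, merge_gap = 0)
  occ1 <- sum(iv1$duration); occ2 <- sum(iv2$duration)
  expect_lte(occ2, occ1)
  # every min_residues=2 occupied frame is occupied at min_residues=1
  f1 <- unlist(mapply(seq, iv1$start_frame, iv1$end_frame, SIMPLIFY = FALSE))
  f2 <- unlist(mapply(seq, iv2$start_frame, iv2$end_frame, SIMPLIFY = FALSE))
  expect_true(all(f2 %in% f1))
})

test_that("binding-site qualification uses a 20% residence fraction", {
  iv70 <- tibble::tibble(ligand = "a", site = "S1", start_frame = 0L,
                         end_frame = 699L, start_time = 0, end_time = 70,
                         duration = 70)
  q <- qualify_binding_site(iv70, run_length = 150)
  expect_true(q$qualified)              # 70/150 = 0.467
  expect_equal(q$total_occupancy, 70)
  iv35 <- dplyr::mutate(iv70, end_frame = 349L, end_time = 35, duration = 35)
  expect_true(qualify_binding_site(iv35, 150)$qualified)  # 35/150 = 0.233
  empty <- iv70[0, ]
  q0 <- qualify_binding_site(empty, 150)
  expect_false(q0$qualified)
  expect_equal(q0$total_occupancy, 0)
  # exact boundary is inclusive
  iv30 <- dplyr::mutate(iv70, end_frame = 299L, end_time = 30, duration = 30)
  expect_true(qualify_binding_site(iv30, 150)$qualified)
  expect_false(qualify_binding_site(iv30, 151)$qualified)
  # intervals past the end of the run are rejected
  bad <- dplyr::mutate(iv70, end_time = 200)
  expect_error(qualify_binding_site(bad, 150), "exceed")
})

test_that("path traces order visits and flag co-visits", {
  synth <- simulate_gas_trajectory(synthetic_spec(
    seed = 4, run_length = 40, frame_interval = 0.1,
    n_o2 = 1, n_no = 0,
    plants = list(plant_dwell("OXY_701", "E1", 2, 5),
                  plant_dwell("OXY_701", "S1", 12, 6),
                  plant_dwell("OXY_701", "CAT", 25, 8))))
  lig <- find_ligands(synth$traj$structure)
  tr <- trace_path(synth$traj, lig[1, ], synth$catalog)
  expect_equal(tr$site, c("E1", "S1", "CAT"))
  expect_equal(tr$entry_time, c(2, 12, 25))
  expect_equal(tr$exit_time, c(7, 18, 33))
  expect_false(any(tr$co_visit))
  # permanently free ligand -> empty trace
  synth2 <- simulate_gas_trajectory(synthetic_spec(
    seed = 5, run_length = 10, frame_interval = 0.1, n_o2 = 1, n_no = 0))
  lig2 <- find_ligands(synth2$traj$structure)
  expect_equal(nrow(trace_path(synth2$traj, lig2[1, ], synth2$catalog)), 0L)
})

test_that("entrance calls follow the most-recent-preceding rule", {
  mk_trace <- function(df) {
    tibble::tibble(ligand = "L", site = df$site,
                   entry_time = df$entry, exit_time = df$entry + 1,
                   start_frame = as.integer(df$entry * 10),
                   end_frame = as.integer(df$entry * 10 + 9),
                   co_visit = FALSE)
  }
  # E1 then catalytic
  tr <- mk_trace(data.frame(site = c("E1", "CAT"), entry = c(10, 40)))
  expect_equal(assign_entrance(tr, frame_interval = 0.1)$call, "E1")
  # E3 first, E1 later: the most recent entrance before CAT wins
  tr2 <- mk_trace(data.frame(site = c("E3", "E1", "CAT"), entry = c(5, 20, 30)))
  out2 <- assign_entrance(tr2, frame_interval = 0.1)
  expect_equal(out2$call, "E1")
  expect_equal(out2$first_entrance_time, 20)
  expect_equal(out2$first_catalytic_time, 30)
  # catalytic never visited -> none
  tr3 <- mk_trace(data.frame(site = c("E1", "S1"), entry = c(5, 10)))
  expect_equal(assign_entrance(tr3, frame_interval = 0.1)$call, "none")
  # first visits within one frame of each other -> ambiguous
  tr4 <- mk_trace(data.frame(site = c("E1", "E3", "CAT"),
                             entry = c(10.0, 10.1, 30)))
  expect_equal(assign_entrance(tr4, frame_interval = 0.1)$call, "ambiguous")
  # catalytic reached with no prior entrance visit -> flagged ambiguous
  tr5 <- mk_trace(data.frame(site = "CAT", entry = 12))
  expect_equal(assign_entrance(tr5, frame_interval = 0.1)$call, "ambiguous")
})

test_that("occupancy intervals partition the occupied frame set exactly", {
  set.seed(9)
  for (i in 1:10) {
    v <- runif(400) < runif(1, 0.1, 0.9)
    tl <- mk_timeline(list("A:1:X" = v))
    iv <- site_occupancy(tl, "S", 0.1, merge_gap = 0)
    frames <- if (nrow(iv)) unlist(mapply(seq, iv$start_frame, iv$end_frame,
                                          SIMPLIFY = FALSE)) else integer(0)
    expect_identical(sort(frames), which(v) - 1L)   # exact partition
    expect_equal(sum(iv$duration), sum(v) * 0.1)    # conservation
    if (nrow(iv) > 1L) {
      expect_true(all(iv$start_frame[-1] > iv$end_frame[-nrow(iv)] + 1L))
    }
  }
})
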