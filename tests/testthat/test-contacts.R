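# Contact detection, timelines, residence times and probabilities.

test_that("the 3.5 Angstrom criterion is strictly exclusive at the boundary", {
  # residues at minimum distances 3.4 / 3.5 / 3.6 from the ligand
  s <- make_structure(resno = c(1L, 2L, 3L, 701L, 701L),
                      resname = c("R1", "R2", "R3", "OXY", "OXY"),
                      x = c(3.4, 3.5, 3.6, 0, 0), y = c(0, 0, 0, 0, 0),
                      z = c(0, 0, 0, 0, 0),
                      element = c("C", "C", "C", "O", "O"))
  fr <- as.matrix(s[, c("x", "y", "z")])
  got <- contact_matrix(s, fr, lig_row(s), c("A:1:R1", "A:2:R2", "A:3:R3"),
                        cutoff = 3.5)
  expect_identical(unname(got), c(TRUE, FALSE, FALSE))
  # coincident atoms are always a contact
  s$x[1] <- 0
  fr <- as.matrix(s[, c("x", "y", "z")])
  expect_true(contact_matrix(s, fr, lig_row(s), "A:1:R1", 3.5)[[1]])
  expect_error(contact_matrix(s, fr, lig_row(s), character(0), 3.5), "empty")
})

test_that("contact_matrix agrees with the brute-force all-pairs oracle", {
  for (seed in 1:6) {
    fx <- random_fixture(n_res = 100, seed = seed)  # ~200 atoms
    fr <- as.matrix(fx[, c("x", "y", "z")])
    lig <- lig_row(fx)
    res <- paste0("A:", 1:100, ":RES")
    got <- contact_matrix(fx, fr, lig, res, cutoff = 6)
    want <- vapply(res, function(r)
      bf_contact(fx, fr, lig$atom_ids[[1]], r, 6), logical(1))
    expect_identical(got, want)
  }
})

test_that("a linear fly-by produces one contact run at the analytic crossing", {
  # ligand centre moves along x at 0.5 A/frame, offset 2 A in y from a
  # point residue at the origin; contact when x^2 + 4 < cutoff^2
  dt <- 0.1; cutoff <- 3.5
  xs <- seq(-10, 10, by = 0.5)
  centres <- cbind(xs, 2, 0)
  tr <- flyby_trajectory(centres, dt = dt)
  lig <- lig_row(tr$structure)
  tl <- contact_timeline(tr, lig, "A:1:RES", cutoff = cutoff)
  runs <- which(tl$contact)
  x_lim <- sqrt(cutoff^2 - 4)  # analytic half-width of the contact window
  expected <- which(abs(xs) < x_lim)
  expect_identical(runs, expected)
  expect_identical(diff(runs), rep(1L, length(runs) - 1L))  # single run
})

test_that("cumulative contact time counts frames and conserves with its complement", {
  tlc <- c(rep(TRUE, 25), rep(FALSE, 75))
  expect_equal(cumulative_contact_time(tlc, 0.1), 2.5)
  expect_equal(cumulative_contact_time(!tlc, 0.1), 10 - 2.5)
  expect_equal(cumulative_contact_time(logical(40), 0.1), 0)
  # property over random timelines
  set.seed(1)
  for (i in 1:20) {
    v <- runif(200) < runif(1)
    expect_equal(cumulative_contact_time(v, 0.1) +
                   cumulative_contact_time(!v, 0.1), 20)
  }
})

test_that("the frequent-contact filter is inclusive at 2.5 ns and rank-ordered", {
  sm <- tibble::tibble(residue = c("A:10:ALA", "A:2:GLY", "A:5:LEU"),
                       n_contact_frames = c(25L, 24L, 30L),
                       cumulative_time = c(2.5, 2.4, 3.0))
  out <- frequent_contact_residues(sm, threshold = 2.5)
  expect_equal(out$residue, c("A:5:LEU", "A:10:ALA"))  # 2.4 excluded, desc order
  # ties broken by ascending residue number
  sm2 <- tibble::tibble(residue = c("A:9:X", "A:3:X"),
                        n_contact_frames = c(30L, 30L),
                        cumulative_time = c(3, 3))
  expect_equal(frequent_contact_residues(sm2, 2.5)$residue,
               c("A:3:X", "A:9:X"))
  # threshold 0 keeps residues with any contact
  sm3 <- tibble::tibble(residue = c("A:1:X", "A:2:X"),
                        n_contact_frames = c(0L, 1L),
                        cumulative_time = c(0, 0.1))
  expect_equal(frequent_contact_residues(sm3, 0)$residue, "A:2:X")
  expect_equal(nrow(frequent_contact_residues(sm3[0, ], 2.5)), 0L)
})

test_that("cross-run aggregation counts qualifying runs without concatenation", {
  run1 <- tibble::tibble(residue = c("A:1:X", "A:2:X"),
                         n_contact_frames = c(30L, 10L),
                         cumulative_time = c(3.0, 1.0))
  run2 <- tibble::tibble(residue = c("A:1:X", "A:2:X"),
                         n_contact_frames = c(28L, 20L),
                         cumulative_time = c(2.8, 2.0))
  agg <- aggregate_runs(list(run1, run2), threshold = 2.5)
  expect_equal(agg$n_runs_observed[agg$residue == "A:1:X"], 2L)
  # 1.0 + 2.0 = 3.0 would pass if concatenated; it must not
  expect_equal(agg$n_runs_observed[agg$residue == "A:2:X"], 0L)
})

test_that("contact probability is the fraction of selected frames in contact", {
  # residue within cutoff in exactly 75 of 100 selected frames
  n <- 100L
  s <- make_structure(resno = c(1L, 2L), resname = c("SAP", "RES"),
                      x = c(0, 0), y = 0, z = 0)
  co <- array(0, c(n, 2, 3))
  co[, 2, 1] <- ifelse(seq_len(n) <= 75, 2, 10)  # 2 A for 75 frames, else 10
  tr <- as_trajectory(s, co, 0.1)
  pr <- contact_probability(tr, 0:(n - 1L), subject_atoms = 1L,
                            residues = "A:2:RES", cutoff = 3.5)
  expect_equal(pr$probability, 0.75)
  pr2 <- contact_probability(tr, 0:74, 1L, "A:2:RES", 3.5)
  expect_equal(pr2$probability, 1.0)
  expect_error(contact_probability(tr, integer(0), 1L, "A:2:RES"),
               "non-empty")
})

test_that("contacts are monotone in the cutoff and order-invariant", {
  for (seed in 7:9) {
    fx <- random_fixture(n_res = 60, seed = seed)
    fr <- as.matrix(fx[, c("x", "y", "z")])
    lig <- lig_row(fx)
    res <- paste0("A:", 1:60, ":RES")
    small <- contact_matrix(fx, fr, lig, res, cutoff = 4)
    large <- contact_matrix(fx, fr, lig, res, cutoff = 9)
    expect_true(all(large[small]))   # enlarging never removes a contact
    shuffled <- sample(res)
    got <- contact_matrix(fx, fr, lig, shuffled, cutoff = 4)
    expect_identical(got[res], small)  # residue order does not matter
    expect_identical(sum(got), sum(small))
  }
})
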