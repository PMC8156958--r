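# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive (triple loops, no vectorisation) and never
# call the package's distance kernels.

# quick structure builder from parallel vectors
make_structure <- function(resno, resname, x, y, z,
                           element = "C", chain = "A", name = "CA") {
  n <- length(resno)
  as_structure(tibble::tibble(
    atom_id = seq_len(n), name = rep_len(name, n),
    element = rep_len(element, n), chain = rep_len(chain, n),
    resno = as.integer(resno), resname = rep_len(resname, n),
    x = x, y = y, z = z
  ))
}

# random multi-residue structure with a gas diatomic appended
random_fixture <- function(n_res, seed, box = 40, atoms_per_res = 2) {
  set.seed(seed)
  n <- n_res * atoms_per_res
  s <- tibble::tibble(
    atom_id = seq_len(n + 2L),
    name = c(rep("CA", n), "O1", "O2"),
    element = c(rep("C", n), "O", "O"),
    chain = "A",
    resno = c(rep(seq_len(n_res), each = atoms_per_res), 701L, 701L),
    resname = c(rep("RES", n), "OXY", "OXY"),
    x = runif(n + 2L, 0, box), y = runif(n + 2L, 0, box),
    z = runif(n + 2L, 0, box)
  )
  as_structure(s)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

# brute-force contact oracle: any ligand-atom / residue-atom pair < cutoff
bf_contact <- function(structure, frame, ligand_atom_ids, residue_key,
                       cutoff) {
  keys <- paste(structure$chain, structure$resno, structure$resname,
                sep = ":")
  lig_rows <- match(ligand_atom_ids, structure$atom_id)
  res_rows <- which(keys == residue_key & structure$element != "H")
  for (i in lig_rows) for (j in res_rows) {
    if (euclid(frame[i, ], frame[j, ]) < cutoff) return(TRUE)
  }
  FALSE
}

# brute-force shell oracle: residues with any heavy atom <= radius of centre
bf_residues_within <- function(structure, frame, center_atom_id, radius) {
  keys <- paste(structure$chain, structure$resno, structure$resname,
                sep = ":")
  c_row <- match(center_atom_id, structure$atom_id)
  hit <- character(0)
  for (i in seq_len(nrow(structure))) {
    if (structure$element[i] == "H") next
    if (euclid(frame[i, ], frame[c_row, ]) <= radius) {
      hit <- c(hit, keys[i])
    }
  }
  sort(unique(hit))
}

# brute-force competent-pose oracle: double loop over frames x O2 instances
bf_competent_poses <- function(traj, refs, ligands, threshold = 7.5) {
  s <- traj$structure
  fe <- match(refs$fe, s$atom_id)
  c13 <- match(refs$c13, s$atom_id)
  c15 <- match(refs$c15, s$atom_id)
  o2 <- ligands[ligands$species == "O2", , drop = FALSE]
  count <- 0L
  for (f in seq_len(dim(traj$coords)[1])) {
    fr <- traj$coords[f, , ]
    d_c13_fe <- euclid(fr[c13, ], fr[fe, ])
    for (i in seq_len(nrow(o2))) {
      rows <- match(o2$atom_ids[[i]], s$atom_id)
      d <- min(euclid(fr[rows[1], ], fr[c15, ]),
               euclid(fr[rows[2], ], fr[c15, ]))
      if (d < threshold && d_c13_fe < threshold) count <- count + 1L
    }
  }
  count
}

# random rigid transform of an n x 3 coordinate matrix
random_rigid <- function(X, seed) {
  set.seed(seed)
  v <- rnorm(3); v <- v / sqrt(sum(v^2)); th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R %*% t(X)) + matrix(runif(3, -20, 20), nrow(X), 3, byrow = TRUE)
}

# single-ligand trajectory from a function frame -> ligand centre position,
# around a fixed one-atom residue at the origin
flyby_trajectory <- function(centres, dt = 0.1, bond = 0) {
  n <- nrow(centres)
  s <- make_structure(resno = c(1L, 701L, 701L), resname = c("RES", "OXY", "OXY"),
                      x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 0, 0),
                      element = c("C", "O", "O"),
                      name = c("CA", "O1", "O2"))
  co <- array(0, c(n, 3, 3))
  for (f in seq_len(n)) {
    co[f, 1, ] <- c(0, 0, 0)
    co[f, 2, ] <- centres[f, ] + c(bond / 2, 0, 0)
    co[f, 3, ] <- centres[f, ] - c(bond / 2, 0, 0)
  }
  as_trajectory(s, co, dt)
}

lig_row <- function(structure, resname = "OXY", resno = 701L,
                    species = "O2") {
  ids <- structure$atom_id[structure$resname == resname &
                             structure$resno == resno]
  tibble::tibble(label = paste0(resname, "_", resno), species = species,
                 chain = "A", resno = resno, atom_ids = list(ids))
}
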