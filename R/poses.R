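# Catalytically competent poses and substrate coordination profiles.

#' Reference atoms for pose-competence analyses
#'
#' @param fe_atom_id Atom id of the catalytic iron.
#' @param c13_atom_id,c15_atom_id Atom ids of the substrate sn-2 chain
#'   carbons C13 and C15 (required by pose analyses; identified by
#'   configured ids, never guessed from names).
#' @param substrate_atom_ids Optional atom ids of the whole substrate.
#' @return A named list of class `lox_refatoms`.
#' @export
reference_atoms <- function(fe_atom_id, c13_atom_id = NULL,
                            c15_atom_id = NULL, substrate_atom_ids = NULL) {
  structure(list(fe = fe_atom_id, c13 = c13_atom_id, c15 = c15_atom_id,
                 substrate = substrate_atom_ids), class = "lox_refatoms")
}

#' Read reference atoms from a YAML config
#'
#' Keys: `fe`, `c13`, `c15`, `substrate` (atom ids).
#' @param path YAML file path.
#' @return `lox_refatoms`.
#' @export
read_reference_atoms <- function(path) {
  if (!file.exists(path)) abort(paste0("reference-atom config not found: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$fe)) abort("reference-atom config must name the iron atom (fe)")
  reference_atoms(y$fe, y$c13, y$c15, unlist(y$substrate))
}

#' Write reference atoms to YAML
#' @param refs `lox_refatoms`.
#' @param path Output path.
#' @export
write_reference_atoms <- function(refs, path) {
  yaml::write_yaml(list(fe = refs$fe, c13 = refs$c13, c15 = refs$c15,
                        substrate = as.list(refs$substrate)), path)
  invisible(path)
}

#' Catalytically competent poses
#'
#' A pose is one (frame, O2 instance) pair in which the O2 molecule is
#' within 7.5 Angstrom (strict `<`) of the substrate carbon C15 while C13
#' is simultaneously within 7.5 Angstrom (strict `<`) of the catalytic
#' iron -- the geometric precondition for peroxidation. Multiple O2
#' molecules satisfying the criterion in the same frame count as separate
#' poses.
#'
#' @param traj A `lox_trajectory`.
#' @param refs [reference_atoms()] carrying `fe`, `c13` and `c15`.
#' @param ligands Ligand tibble from [find_ligands()]; only rows with
#'   species `"O2"` are considered.
#' @param threshold Angstrom; default 7.5 (applies to both conditions).
#' @return Tibble `frame`, `time`, `o2_label`, `d_o2_c15`, `d_c13_fe`,
#'   sorted by frame then label.
#' @export
competent_poses <- function(traj, refs, ligands, threshold = 7.5) {
  stopifnot_scalar_pos(threshold, "threshold")
  if (is.null(refs$fe) || is.null(refs$c13) || is.null(refs$c15)) {
    abort("competent_poses needs fe, c13 and c15 reference atoms")
  }
  o2 <- ligands[ligands$species == "O2", , drop = FALSE]
  if (!nrow(o2)) abort("no O2 ligand instances supplied")
  s <- traj$structure
  d_c13_fe <- traj_min_dist(traj, atom_rows(s, refs$c13),
                            atom_rows(s, refs$fe))
  times <- frame_times(traj)
  pieces <- lapply(seq_len(nrow(o2)), function(i) {
    lig <- ligand_info(s, o2[i, ])
    d <- traj_min_dist(traj, lig$rows, atom_rows(s, refs$c15))
    ok <- d < threshold & d_c13_fe < threshold
    tibble(frame = which(ok) - 1L, time = times[ok], o2_label = lig$label,
           d_o2_c15 = d[ok], d_c13_fe = d_c13_fe[ok])
  })
  out <- bind_rows(pieces)
  arrange(out, .data$frame, .data$o2_label)
}

#' Substrate coordination profile over selected frames
#'
#' Contact probability of candidate residues with the substrate over a
#' frame selection (by default the competent-pose frames), delegating to
#' [contact_probability()]. Residues at or above `report_threshold` are
#' flagged as high-propensity coordinators.
#'
#' @param traj A `lox_trajectory`.
#' @param selected_frames 0-based frame indices (e.g.
#'   `unique(competent_poses(...)$frame)`).
#' @param substrate_atom_ids Atom ids of the substrate.
#' @param candidate_residues Residue keys (may span chains, e.g. enzyme and
#'   partner-protein residues in one profile).
#' @param cutoff Contact cutoff, Angstrom; default 3.5.
#' @param report_threshold Probability above which a residue is flagged;
#'   default 0.70.
#' @return Tibble `residue`, `n_contact`, `probability`, `high_propensity`,
#'   with `n_selected_frames` and `source` as attributes.
#' @export
coordination_profile <- function(traj, selected_frames, substrate_atom_ids,
                                 candidate_residues, cutoff = 3.5,
                                 report_threshold = 0.70) {
  if (!length(selected_frames)) abort("selected_frames must be non-empty")
  out <- contact_probability(traj, selected_frames, substrate_atom_ids,
                             candidate_residues, cutoff = cutoff)
  out$high_propensity <- out$probability >= report_threshold
  attr(out, "n_selected_frames") <- length(unique(selected_frames))
  attr(out, "source") <- "custom selection"
  out
}
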