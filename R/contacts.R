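# Ligand-residue contact analysis: per-frame contacts, timelines, residence
# times, frequent-contact filters and contact probabilities.

# Resolve a ligand argument (one row of find_ligands(), or a list with
# $label and $atom_ids) to structure row indices + label.
ligand_info <- function(structure, ligand) {
  if (is.data.frame(ligand)) {
    if (nrow(ligand) != 1L) abort("pass exactly one ligand (one row)")
    ids <- ligand$atom_ids[[1]]
    label <- ligand$label[[1]]
  } else {
    ids <- ligand$atom_ids
    label <- ligand$label
  }
  list(label = label, rows = atom_rows(structure, ids))
}

#' Per-frame ligand-residue contact vector
#'
#' A residue is in contact when any ligand-atom/residue-atom pair (heavy
#' atoms by default) is at a distance strictly less than `cutoff`.
#'
#' @param structure A `lox_structure`.
#' @param frame n_atoms x 3 coordinate matrix for one frame.
#' @param ligand One ligand (a row of [find_ligands()]).
#' @param residues Character vector of residue keys.
#' @param cutoff Contact cutoff in Angstrom; default 3.5.
#' @param include_hydrogens Include hydrogens on the residue side.
#' @param box Optional periodic box lengths.
#' @return Named logical vector over `residues`.
#' @export
contact_matrix <- function(structure, frame, ligand, residues, cutoff = 3.5,
                           include_hydrogens = FALSE, box = NULL) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  if (!length(residues)) abort("empty residue selection")
  lig <- ligand_info(structure, ligand)
  out <- setNames(logical(length(residues)), residues)
  L <- frame[lig$rows, , drop = FALSE]
  for (r in residues) {
    rows <- residue_atom_rows(structure, r, include_hydrogens)
    if (!length(rows)) abort(paste0("residue ", r, " resolves to no atoms"))
    d2 <- cross_dist2(L, frame[rows, , drop = FALSE], box = box)
    out[[r]] <- min(d2) < cutoff^2
  }
  out
}

#' Contact timeline of a ligand against a residue set
#'
#' One row per (residue, frame) with the contact flag and the minimum
#' ligand-residue heavy-atom distance, in long (tidy) form.
#'
#' @param traj A `lox_trajectory`.
#' @param ligand One ligand (a row of [find_ligands()]).
#' @param residues Character vector of residue keys.
#' @param cutoff Contact cutoff in Angstrom (strict `<`); default 3.5.
#' @param include_hydrogens Include hydrogens on the residue side.
#' @return Tibble `ligand`, `residue`, `frame` (0-based), `time` (ns),
#'   `min_distance`, `contact`.
#' @export
contact_timeline <- function(traj, ligand, residues, cutoff = 3.5,
                             include_hydrogens = FALSE) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  if (!length(residues)) abort("empty residue selection")
  s <- traj$structure
  lig <- ligand_info(s, ligand)
  nf <- n_frames(traj)
  times <- frame_times(traj)
  pieces <- lapply(residues, function(r) {
    rows <- residue_atom_rows(s, r, include_hydrogens)
    if (!length(rows)) abort(paste0("residue ", r, " resolves to no atoms"))
    md <- traj_min_dist(traj, lig$rows, rows)
    tibble(ligand = lig$label, residue = r, frame = 0:(nf - 1L),
           time = times, min_distance = md, contact = md < cutoff)
  })
  bind_rows(pieces)
}

#' Cumulative contact time of a timeline
#'
#' @param contact Logical per-frame contact vector, or a timeline tibble for
#'   a single residue (its `contact` column is used).
#' @param frame_interval ns per frame.
#' @return Cumulative contact time in ns.
#' @export
cumulative_contact_time <- function(contact, frame_interval) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (is.data.frame(contact)) contact <- contact$contact
  sum(as.logical(contact)) * frame_interval
}

#' Per-residue contact summary of a timeline set
#'
#' @param timelines Timeline tibble from [contact_timeline()] (may span
#'   several residues and ligands; summaries pool ligands per residue).
#' @param frame_interval ns per frame.
#' @return Tibble `residue`, `n_contact_frames`, `cumulative_time` (ns).
#' @export
contact_summary <- function(timelines, frame_interval) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  timelines %>%
    group_by(.data$residue) %>%
    summarise(n_contact_frames = sum(.data$contact), .groups = "drop") %>%
    mutate(cumulative_time = .data$n_contact_frames * frame_interval)
}

#' Residues with frequent contacts
#'
#' Keeps residues whose cumulative contact time reaches `threshold`
#' (inclusive), sorted by descending cumulative time with ties broken by
#' ascending residue number.
#'
#' @param summaries Tibble from [contact_summary()] (columns `residue`,
#'   `cumulative_time`).
#' @param threshold Minimum cumulative contact time in ns; default 2.5.
#' @return Tibble of the retained rows, in rank order.
#' @export
frequent_contact_residues <- function(summaries, threshold = 2.5) {
  if (threshold < 0) abort("threshold must be >= 0")
  if (!nrow(summaries)) return(summaries)
  keep <- summaries[summaries$cumulative_time >= threshold, , drop = FALSE]
  # at threshold 0 the filter means "any contact at all"
  if (threshold == 0) keep <- keep[keep$cumulative_time > 0, , drop = FALSE]
  keep[order(-keep$cumulative_time, res_key_number(keep$residue)), ]
}

#' Cross-run frequent-contact statistics
#'
#' Runs are independent inputs and are never concatenated: a residue's
#' `n_runs_observed` counts the runs in which its cumulative contact time
#' reaches the frequent-contact threshold.
#'
#' @param summaries_by_run List of [contact_summary()] tibbles, one per run.
#' @param threshold Frequent-contact threshold in ns; default 2.5.
#' @return Tibble `residue`, `n_runs_observed`, `mean_cumulative_time`,
#'   `total_cumulative_time`, sorted by descending `n_runs_observed` then
#'   residue number.
#' @export
aggregate_runs <- function(summaries_by_run, threshold = 2.5) {
  if (!length(summaries_by_run)) {
    return(tibble(residue = character(), n_runs_observed = integer(),
                  mean_cumulative_time = double(),
                  total_cumulative_time = double()))
  }
  all <- bind_rows(lapply(seq_along(summaries_by_run), function(i) {
    mutate(summaries_by_run[[i]], run = i)
  }))
  out <- all %>%
    group_by(.data$residue) %>%
    summarise(
      n_runs_observed = sum(.data$cumulative_time >= threshold),
      mean_cumulative_time = mean(.data$cumulative_time),
      total_cumulative_time = sum(.data$cumulative_time),
      .groups = "drop"
    )
  out[order(-out$n_runs_observed, res_key_number(out$residue)), ]
}

#' Contact probability over selected frames
#'
#' For each candidate residue, the number of selected frames in which any
#' subject-atom/residue-atom pair is within `cutoff` (strict `<`), divided
#' by the number of selected frames.
#'
#' @param traj A `lox_trajectory`.
#' @param selected_frames 0-based frame indices (non-empty).
#' @param subject_atoms Atom ids of the subject (e.g. the substrate).
#' @param residues Candidate residue keys (may span chains).
#' @param cutoff Angstrom; default 3.5.
#' @param include_hydrogens Include hydrogens on the residue side.
#' @return Tibble `residue`, `n_contact`, `probability` sorted by residue
#'   number.
#' @export
contact_probability <- function(traj, selected_frames, subject_atoms,
                                residues, cutoff = 3.5,
                                include_hydrogens = FALSE) {
  if (!length(selected_frames)) abort("selected_frames must be non-empty")
  stopifnot_scalar_pos(cutoff, "cutoff")
  if (any(selected_frames < 0 | selected_frames >= n_frames(traj))) {
    abort("selected_frames out of range")
  }
  s <- traj$structure
  srows <- atom_rows(s, subject_atoms)
  sel1 <- as.integer(selected_frames) + 1L
  sub <- traj
  sub$coords <- traj$coords[sel1, , , drop = FALSE]
  pieces <- lapply(residues, function(r) {
    rows <- residue_atom_rows(s, r, include_hydrogens)
    if (!length(rows)) abort(paste0("residue ", r, " resolves to no atoms"))
    md <- traj_min_dist(sub, srows, rows)
    tibble(residue = r, n_contact = sum(md < cutoff))
  })
  out <- bind_rows(pieces) %>%
    mutate(probability = .data$n_contact / length(selected_frames))
  out[order(res_key_number(out$residue)), ]
}
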