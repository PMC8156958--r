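# Two-species competition near a target atom: proximity series,
# co-localization and displacement events.

#' Proximity series of a ligand to a target atom
#'
#' Per-frame distance of the ligand to a target atom (for a diatomic, the
#' minimum over its two atoms: nearest-atom semantics consistent with
#' contact analysis), plus a thresholded `within` flag (inclusive `<=`).
#'
#' @param traj A `lox_trajectory`.
#' @param ligand One ligand (a row of [find_ligands()]).
#' @param target_atom_id Atom id of the target (e.g. the substrate carbon
#'   C15, or the catalytic iron).
#' @param threshold Angstrom (> 0); e.g. 7.5 for the catalytic-pocket
#'   proximity criterion.
#' @return Tibble `ligand`, `frame`, `time`, `distance`, `within`, with the
#'   target atom id and threshold in attributes `target` and `threshold`.
#' @export
proximity_series <- function(traj, ligand, target_atom_id, threshold) {
  stopifnot_scalar_pos(threshold, "threshold")
  s <- traj$structure
  lig <- ligand_info(s, ligand)
  trow <- atom_rows(s, target_atom_id)
  d <- traj_min_dist(traj, lig$rows, trow)
  out <- tibble(ligand = lig$label, frame = 0:(n_frames(traj) - 1L),
                time = frame_times(traj), distance = d,
                within = d <= threshold)
  attr(out, "target") <- target_atom_id
  attr(out, "threshold") <- threshold
  out
}

check_series_compatible <- function(series_list) {
  t0 <- attr(series_list[[1]], "target")
  th0 <- attr(series_list[[1]], "threshold")
  n0 <- nrow(series_list[[1]])
  for (s in series_list[-1]) {
    if (!identical(attr(s, "target"), t0) ||
        !identical(attr(s, "threshold"), th0) || nrow(s) != n0) {
      abort("proximity series disagree in target, threshold or length")
    }
  }
  invisible(TRUE)
}

#' Fraction of frames in which two ligands are both near the target
#'
#' @param series_a,series_b [proximity_series()] tibbles over the same
#'   target, threshold and frames.
#' @return Fraction in `[0, 1]`.
#' @export
colocalization_fraction <- function(series_a, series_b) {
  check_series_compatible(list(series_a, series_b))
  mean(series_a$within & series_b$within)
}

#' Detect displacement events among competing ligands
#'
#' Ligand A is displaced by ligand B when: A is continuously within the
#' threshold for at least `min_pre_dwell`; B first comes within during A's
#' occupancy (or within `max_entry_gap` after its end); A then leaves and
#' stays out for at least `min_post_absence` (absence runs truncated by the
#' end of the trajectory count at face value); and B is still within when A
#' has left. The three-parameter rule is this package's operational
#' formalization of a qualitatively described competition process, and is
#' labelled as such in reports.
#'
#' @param series_by_ligand List of [proximity_series()] tibbles, one per
#'   ligand, sharing target and threshold.
#' @param min_pre_dwell Minimum dwell of the displaced ligand before the
#'   event, ns; default 5.
#' @param max_entry_gap Maximum lag between the displaced ligand's exit and
#'   the displacer's entry, ns; default 1.
#' @param min_post_absence Minimum absence of the displaced ligand after
#'   the event, ns; default 5.
#' @param frame_interval ns per frame; default taken from consecutive
#'   series times.
#' @return Tibble `displaced`, `displacer`, `overlap_start` (ns; the
#'   displacer's qualifying entry), `displacement_time` (ns; the first
#'   frame the displaced ligand is out), plus the parameters used as
#'   attributes; ordered by `displacement_time`.
#' @export
detect_displacements <- function(series_by_ligand, min_pre_dwell = 5,
                                 max_entry_gap = 1, min_post_absence = 5,
                                 frame_interval = NULL) {
  if (!length(series_by_ligand)) {
    abort("series_by_ligand must contain at least one series")
  }
  check_series_compatible(series_by_ligand)
  if (is.null(frame_interval)) {
    tm <- series_by_ligand[[1]]$time
    frame_interval <- if (length(tm) > 1L) tm[2] - tm[1] else 1
  }
  nf <- nrow(series_by_ligand[[1]])
  labels <- vapply(series_by_ligand, function(s) s$ligand[1], character(1))
  within <- lapply(series_by_ligand, function(s) s$within)
  names(within) <- labels
  empty <- tibble(displaced = character(), displacer = character(),
                  overlap_start = double(), displacement_time = double())
  events <- list()
  for (a in labels) {
    runs_a <- bool_runs(within[[a]])
    for (ri in seq_len(nrow(runs_a))) {
      s <- runs_a$start[ri]; e <- runs_a$end[ri]
      dwell <- (e - s + 1L) * frame_interval
      if (dwell < min_pre_dwell - 1e-9) next
      # A must stay out for min_post_absence after frame e
      nxt <- runs_a$start[runs_a$start > e]
      absence_frames <- if (length(nxt)) min(nxt) - e - 1L else nf - 1L - e
      if (absence_frames * frame_interval < min_post_absence - 1e-9) next
      if (e >= nf - 1L) next  # run extends to the final frame: no exit
      exit_frame <- e + 1L
      for (b in setdiff(labels, a)) {
        runs_b <- bool_runs(within[[b]])
        if (!nrow(runs_b)) next
        # B's qualifying entry: a run start inside [s, e + max_entry_gap]
        gapf <- floor(max_entry_gap / frame_interval + 1e-9)
        cand <- runs_b$start[runs_b$start >= s & runs_b$start <= e + gapf]
        if (!length(cand)) next
        # B must still be within once A has left: either B is present at
        # A's exit frame, or a qualifying B entry falls in the entry gap
        b_at_exit <- isTRUE(within[[b]][min(exit_frame, nf - 1L) + 1L])
        entry <- if (b_at_exit) min(cand) else {
          gap_entries <- cand[cand > e]
          if (!length(gap_entries)) next
          min(gap_entries)
        }
        events[[length(events) + 1L]] <- tibble(
          displaced = a, displacer = b,
          overlap_start = entry * frame_interval,
          displacement_time = exit_frame * frame_interval
        )
      }
    }
  }
  out <- if (length(events)) arrange(bind_rows(events),
                                     .data$displacement_time,
                                     .data$displaced, .data$displacer)
         else empty
  attr(out, "parameters") <- list(
    threshold = attr(series_by_ligand[[1]], "threshold"),
    min_pre_dwell = min_pre_dwell, max_entry_gap = max_entry_gap,
    min_post_absence = min_post_absence
  )
  out
}
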