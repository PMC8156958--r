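# Named-site machinery: catalogs, occupancy intervals, binding-site
# qualification, path traces and entrance assignment.

#' Read a site catalog
#'
#' A site catalog is YAML of the form
#' ```yaml
#' sites:
#'   E1: {role: entrance, residues: [A:154:TYR, A:155:ASN]}
#' ```
#' Residue keys are `"chain:resno:resname"`.
#'
#' @param path Path to the YAML catalog.
#' @return Tibble `site`, `role`, `residues` (list-column of residue keys).
#' @export
read_site_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("site catalog not found: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$sites) || !length(y$sites)) abort("catalog has no sites")
  out <- bind_rows(lapply(names(y$sites), function(nm) {
    s <- y$sites[[nm]]
    if (!length(s$residues)) abort(paste0("site ", nm, " has no residues"))
    tibble(site = nm, role = s$role %||% "binding",
           residues = list(unlist(s$residues)))
  }))
  if (anyDuplicated(out$site)) abort("duplicate site names in catalog")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a site catalog
#' @param catalog Tibble as returned by [read_site_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(catalog, path) {
  sites <- setNames(lapply(seq_len(nrow(catalog)), function(i) {
    list(role = catalog$role[i], residues = as.list(catalog$residues[[i]]))
  }), catalog$site)
  yaml::write_yaml(list(sites = sites), path)
  invisible(path)
}

#' Reference site catalog for human 15LOX-2
#'
#' Entrances, binding sites, the catalytic site, hydrophobic clusters and
#' the wide-entrance tunnel of 15-lipoxygenase-2, as residue sets on chain
#' A of the 4NRE numbering. `S0` (the first-recognition site) shares the E1
#' residue set with role `binding`.
#'
#' @return Site catalog tibble.
#' @export
lox2_site_catalog <- function() {
  read_site_catalog(system.file("extdata", "sites_15lox2.yaml",
                                package = "loxtraj", mustWork = TRUE))
}

#' Residue keys of one site in a catalog
#' @param catalog Site catalog tibble.
#' @param site Site name.
#' @export
site_residues <- function(catalog, site) {
  i <- match(site, catalog$site)
  if (is.na(i)) abort(paste0("site ", site, " not in catalog"))
  catalog$residues[[i]]
}

#' Occupancy intervals of a ligand at a site
#'
#' A frame is occupied when the ligand contacts at least `min_residues` of
#' the site's residues; occupied runs separated by gaps of at most
#' `merge_gap` ns are merged (the annexed gap frames count as occupied in
#' the interval duration). Set `merge_gap = 0` for an exact partition of
#' the occupied frame set.
#'
#' @param timelines [contact_timeline()] tibble for one ligand covering all
#'   of the site's residues.
#' @param site Site name (string) or one catalog row; used for labelling
#'   and to check residue coverage when residues are known.
#' @param frame_interval ns per frame.
#' @param site_residues Optional character vector of the site's residue
#'   keys; defaults to the residues present in `timelines`.
#' @param min_residues Minimum simultaneously contacted residues; default 1.
#' @param merge_gap Maximum gap to merge, ns; default 0.5.
#' @return Tibble `ligand`, `site`, `start_frame`, `end_frame` (inclusive,
#'   0-based), `start_time`, `end_time` (ns, end exclusive), `duration`
#'   (ns), sorted and disjoint.
#' @export
site_occupancy <- function(timelines, site, frame_interval,
                           site_residues = NULL, min_residues = 1L,
                           merge_gap = 0.5) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (min_residues < 1L) abort("min_residues must be >= 1")
  if (merge_gap < 0) abort("merge_gap must be >= 0")
  site_name <- if (is.data.frame(site)) site$site[[1]] else site
  if (is.null(site_residues)) site_residues <- unique(timelines$residue)
  missing_res <- setdiff(site_residues, unique(timelines$residue))
  if (length(missing_res)) {
    abort(paste0("timelines missing site residue(s): ",
                 paste(missing_res, collapse = ", ")))
  }
  lig <- unique(timelines$ligand)
  if (length(lig) != 1L) abort("site_occupancy expects one ligand's timelines")
  tl <- timelines[timelines$residue %in% site_residues, , drop = FALSE]
  counts <- tapply(tl$contact, tl$frame, sum)
  frames <- as.integer(names(counts))
  occupied <- logical(max(frames) + 1L)
  occupied[frames + 1L] <- counts >= min_residues
  runs <- bool_runs(occupied)
  gap_frames <- floor(merge_gap / frame_interval + 1e-9)
  runs <- merge_runs(runs, gap_frames)
  if (!nrow(runs)) {
    return(tibble(ligand = character(), site = character(),
                  start_frame = integer(), end_frame = integer(),
                  start_time = double(), end_time = double(),
                  duration = double()))
  }
  tibble(
    ligand = lig, site = site_name,
    start_frame = runs$start, end_frame = runs$end,
    start_time = runs$start * frame_interval,
    end_time = (runs$end + 1L) * frame_interval,
    duration = (runs$end - runs$start + 1L) * frame_interval
  )
}

#' Qualify a site as a binding site by total residence
#'
#' A site qualifies when the summed occupancy across its intervals reaches
#' `min_fraction` of the run length. Both binding sites reported for
#' 15LOX-2 (occupied >70 ns and >35 ns of 150 ns runs) pass at the default
#' fraction 0.20.
#'
#' @param intervals [site_occupancy()] tibble (possibly empty).
#' @param run_length Total trajectory time, ns.
#' @param min_fraction Qualification fraction of the run length; default 0.20.
#' @return Tibble with one row: `qualified`, `total_occupancy` (ns),
#'   `longest` (ns), `n_intervals`, `fraction`.
#' @export
qualify_binding_site <- function(intervals, run_length, min_fraction = 0.20) {
  stopifnot_scalar_pos(run_length, "run_length")
  if (nrow(intervals) && max(intervals$end_time) > run_length + 1e-9) {
    abort("occupancy intervals exceed the stated run length")
  }
  total <- if (nrow(intervals)) sum(intervals$duration) else 0
  longest <- if (nrow(intervals)) max(intervals$duration) else 0
  tibble(
    qualified = total >= min_fraction * run_length - 1e-9,
    total_occupancy = total, longest = longest,
    n_intervals = nrow(intervals),
    fraction = total / run_length
  )
}

#' Trace a ligand's path through a site catalog
#'
#' Builds per-site occupancy and returns the time-ordered visit list.
#' Frames during which the ligand satisfies the occupancy rule for more
#' than one site produce one visit row per site, flagged `co_visit`.
#'
#' @param traj A `lox_trajectory`.
#' @param ligand One ligand (a row of [find_ligands()]).
#' @param catalog Site catalog tibble.
#' @param cutoff Contact cutoff, Angstrom; default 3.5.
#' @param min_residues,merge_gap Passed to [site_occupancy()].
#' @return Tibble `ligand`, `site`, `entry_time`, `exit_time`,
#'   `start_frame`, `end_frame`, `co_visit`, ordered by `entry_time`.
#' @export
trace_path <- function(traj, ligand, catalog, cutoff = 3.5,
                       min_residues = 1L, merge_gap = 0.5) {
  if (!nrow(catalog)) abort("site catalog is empty")
  dt <- traj$frame_interval
  visits <- bind_rows(lapply(seq_len(nrow(catalog)), function(i) {
    tl <- contact_timeline(traj, ligand, catalog$residues[[i]], cutoff = cutoff)
    site_occupancy(tl, catalog$site[i], dt,
                   site_residues = catalog$residues[[i]],
                   min_residues = min_residues, merge_gap = merge_gap)
  }))
  if (!nrow(visits)) {
    return(tibble(ligand = character(), site = character(),
                  entry_time = double(), exit_time = double(),
                  start_frame = integer(), end_frame = integer(),
                  co_visit = logical()))
  }
  visits <- visits %>%
    mutate(entry_time = .data$start_time, exit_time = .data$end_time) %>%
    arrange(.data$entry_time, .data$site)
  # flag co-visits: overlap in frames with a visit to a different site
  co <- vapply(seq_len(nrow(visits)), function(i) {
    any(visits$site != visits$site[i] &
          visits$start_frame <= visits$end_frame[i] &
          visits$end_frame >= visits$start_frame[i])
  }, logical(1))
  visits$co_visit <- co
  select(visits, "ligand", "site", "entry_time", "exit_time",
         "start_frame", "end_frame", "co_visit")
}

#' Assign the entrance used to reach the catalytic site
#'
#' The call is the entrance whose first visit most recently precedes the
#' first catalytic-site visit; `none` when the catalytic site is never
#' visited; `ambiguous` when the two entrances' first visits fall within
#' one frame of each other before the catalytic visit (or when the
#' catalytic site is reached without any preceding entrance visit).
#'
#' @param trace [trace_path()] tibble for one ligand.
#' @param entrances Entrance site names; default `c("E1", "E3")`.
#' @param catalytic Catalytic site name; default `"CAT"`.
#' @param frame_interval ns per frame (defines the one-frame ambiguity
#'   window).
#' @param first_catalytic_time Optional override for the first catalytic
#'   contact time (e.g. from an iron-proximity series); defaults to the
#'   first visit of `catalytic` in the trace.
#' @return Tibble with one row: `ligand`, `call`, `first_entrance_time`,
#'   `first_catalytic_time`.
#' @export
assign_entrance <- function(trace, entrances = c("E1", "E3"),
                            catalytic = "CAT", frame_interval = 0.1,
                            first_catalytic_time = NULL) {
  lig <- if (nrow(trace)) unique(trace$ligand) else NA_character_
  if (length(lig) != 1L) lig <- lig[1]
  if (is.null(first_catalytic_time)) {
    cat_visits <- trace[trace$site == catalytic, , drop = FALSE]
    first_catalytic_time <-
      if (nrow(cat_visits)) min(cat_visits$entry_time) else NA_real_
  }
  if (is.na(first_catalytic_time)) {
    return(tibble(ligand = lig, call = "none",
                  first_entrance_time = NA_real_,
                  first_catalytic_time = NA_real_))
  }
  firsts <- vapply(entrances, function(e) {
    v <- trace[trace$site == e & trace$entry_time <= first_catalytic_time, ,
               drop = FALSE]
    if (nrow(v)) min(v$entry_time) else NA_real_
  }, double(1))
  seen <- firsts[!is.na(firsts)]
  if (!length(seen)) {
    return(tibble(ligand = lig, call = "ambiguous",
                  first_entrance_time = NA_real_,
                  first_catalytic_time = first_catalytic_time))
  }
  latest <- max(seen)
  winners <- names(seen)[seen >= latest - frame_interval - 1e-9]
  call <- if (length(winners) > 1L) "ambiguous" else winners
  tibble(ligand = lig, call = call,
         first_entrance_time = latest,
         first_catalytic_time = first_catalytic_time)
}
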