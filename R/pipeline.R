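# End-to-end pipeline driver: contacts -> sites -> paths/entrances ->
# competition -> poses -> profiles, with TSV outputs, a parameter-audit run
# log and a machine-readable JSON summary.

default_parameters <- function() {
  list(
    contact_cutoff = 3.5,    # strict-< ligand-residue contact, Angstrom
    frequent_threshold = 2.5, # inclusive cumulative-contact filter, ns
    pose_threshold = 7.5,    # strict-< dual pose criterion, Angstrom
    sape_proximity = 7.0,    # inclusive substrate-proximity shell, Angstrom
    fe_shell = 20.0,         # inclusive iron shell for residue statistics
    qualify_fraction = 0.20, # binding-site qualification fraction
    min_residues = 1,        # site-occupancy membership
    merge_gap = 0.5,         # occupancy gap merging, ns
    min_pre_dwell = 5,       # displacement: dwell before event, ns
    max_entry_gap = 1,       # displacement: displacer entry lag, ns
    min_post_absence = 5,    # displacement: absence after event, ns
    report_threshold = 0.70  # coordination-profile flag level
  )
}

#' Assemble a pipeline run configuration
#'
#' @param structure,trajectory,sites,refs Input file paths (structure,
#'   trajectory, site catalog YAML, reference-atoms YAML).
#' @param frame_interval ns per frame.
#' @param output_dir Directory for tables, log and summary.
#' @param parameters Named list overriding entries of the default analysis
#'   parameter block.
#' @param seed Seed recorded in the log (used by synthetic subworkflows).
#' @return List of class `lox_config`.
#' @export
run_config <- function(structure, trajectory, sites, refs,
                       frame_interval = 0.1, output_dir,
                       parameters = list(), seed = NULL) {
  pars <- utils::modifyList(default_parameters(), parameters)
  bad <- names(pars)[vapply(pars, function(p) !is.numeric(p) || p < 0,
                            logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric or negative parameter(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(structure = structure, trajectory = trajectory,
                 sites = sites, refs = refs,
                 frame_interval = frame_interval,
                 output_dir = output_dir, parameters = pars, seed = seed),
            class = "lox_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML config path.
#' @return `lox_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  for (nm in c("structure", "trajectory", "sites", "refs", "output_dir")) {
    if (is.null(y[[nm]])) abort(paste0("config is missing '", nm, "'"))
  }
  run_config(y$structure, y$trajectory, y$sites, y$refs,
             frame_interval = y$frame_interval %||% 0.1,
             output_dir = y$output_dir,
             parameters = y$parameters %||% list(), seed = y$seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes contact, site-occupancy, path/entrance, competition, pose and
#' coordination analyses on one trajectory, writes TSV tables, a run log
#' echoing every parameter, and a JSON summary. Deterministic given
#' identical inputs.
#'
#' @param config A `lox_config` (or path to a YAML config).
#' @return Invisible list of class `lox_report` with all result tibbles and
#'   the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "lox_config"))
  for (nm in c("structure", "trajectory", "sites", "refs")) {
    if (!file.exists(config[[nm]])) {
      abort(paste0("missing input '", nm, "': ", config[[nm]]))
    }
  }
  pars <- config$parameters
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("loxtraj pipeline run log",
                 paste0("input structure = ", config$structure),
                 paste0("input trajectory = ", config$trajectory),
                 paste0("input sites = ", config$sites),
                 paste0("input refs = ", config$refs),
                 paste0("frame_interval = ", config$frame_interval),
                 paste0("seed = ", config$seed %||% "none"),
                 vapply(names(pars), function(nm)
                   paste0("parameter ", nm, " = ", format(pars[[nm]])),
                   character(1)))

  struct <- stage("load", load_structure(config$structure))
  traj <- stage("load", load_trajectory(config$trajectory, struct,
                                        frame_interval = config$frame_interval))
  catalog <- stage("load", read_site_catalog(config$sites))
  refs <- stage("load", read_reference_atoms(config$refs))
  ligands <- stage("ligands", find_ligands(struct))
  if (!nrow(ligands)) abort("pipeline stage 'ligands' failed: no gas ligands found")
  dt <- traj$frame_interval
  rl <- run_length(traj)

  # sites: traces, occupancy, qualification -------------------------------
  traces <- stage("sites", bind_rows(lapply(seq_len(nrow(ligands)), function(i)
    trace_path(traj, ligands[i, ], catalog, cutoff = pars$contact_cutoff,
               min_residues = pars$min_residues, merge_gap = pars$merge_gap))))
  occupancy <- traces %>%
    mutate(duration = (.data$end_frame - .data$start_frame + 1L) * dt)
  qualification <- stage("sites", bind_rows(lapply(catalog$site, function(snm) {
    iv <- occupancy[occupancy$site == snm, , drop = FALSE]
    iv$start_time <- iv$entry_time; iv$end_time <- iv$exit_time
    q <- qualify_binding_site(iv, rl, min_fraction = pars$qualify_fraction)
    mutate(q, site = snm, .before = 1)
  })))

  # entrances --------------------------------------------------------------
  fe_series <- stage("entrances", lapply(seq_len(nrow(ligands)), function(i)
    proximity_series(traj, ligands[i, ], refs$fe, threshold = pars$pose_threshold)))
  entrance_calls <- stage("entrances", bind_rows(
    lapply(seq_len(nrow(ligands)), function(i) {
      tr <- traces[traces$ligand == ligands$label[i], , drop = FALSE]
      fs <- fe_series[[i]]
      fe_first <- if (any(fs$within)) min(fs$time[fs$within]) else NA_real_
      cat_visits <- tr[tr$site == "CAT", , drop = FALSE]
      cat_first <- if (nrow(cat_visits)) min(cat_visits$entry_time) else NA_real_
      first_cat <- suppressWarnings(min(c(fe_first, cat_first), na.rm = TRUE))
      if (!is.finite(first_cat)) first_cat <- NULL
      assign_entrance(tr, frame_interval = dt, first_catalytic_time = first_cat)
    })))

  # competition near C15 ----------------------------------------------------
  competition <- stage("competition", {
    if (!is.null(refs$c15)) {
      series <- lapply(seq_len(nrow(ligands)), function(i)
        proximity_series(traj, ligands[i, ], refs$c15,
                         threshold = pars$pose_threshold))
      ev <- detect_displacements(series,
                                 min_pre_dwell = pars$min_pre_dwell,
                                 max_entry_gap = pars$max_entry_gap,
                                 min_post_absence = pars$min_post_absence,
                                 frame_interval = dt)
      o2_within <- Reduce(`|`, lapply(which(ligands$species == "O2"),
                                      function(i) series[[i]]$within),
                          accumulate = FALSE, right = FALSE,
                          init = rep(FALSE, n_frames(traj)))
      no_within <- Reduce(`|`, lapply(which(ligands$species == "NO"),
                                      function(i) series[[i]]$within),
                          init = rep(FALSE, n_frames(traj)))
      list(events = ev, species_colocalization = mean(o2_within & no_within))
    } else list(events = tibble(displaced = character(),
                                displacer = character(),
                                overlap_start = double(),
                                displacement_time = double()),
                species_colocalization = NA_real_)
  })

  # poses and coordination profile ------------------------------------------
  poses <- stage("poses", {
    if (any(ligands$species == "O2") && !is.null(refs$c13) &&
        !is.null(refs$c15)) {
      competent_poses(traj, refs, ligands, threshold = pars$pose_threshold)
    } else tibble(frame = integer(), time = double(), o2_label = character(),
                  d_o2_c15 = double(), d_c13_fe = double())
  })
  profile <- stage("profile", {
    if (nrow(poses) && length(refs$substrate)) {
      shell <- residues_within(struct, center_atom_id = refs$fe,
                               radius = pars$fe_shell)
      shell <- setdiff(shell, res_key(struct$chain, struct$resno,
                                      struct$resname)[
                         struct$resname %in% c("OXY", "NO")])
      coordination_profile(traj, unique(poses$frame), refs$substrate,
                           shell, cutoff = pars$contact_cutoff,
                           report_threshold = pars$report_threshold)
    } else tibble(residue = character(), n_contact = integer(),
                  probability = double(), high_propensity = logical())
  })

  # substrate proximity fractions (co-localization shell around the lipid)
  sape_fraction <- stage("profile", {
    if (length(refs$substrate)) {
      srows <- atom_rows(struct, refs$substrate)
      bind_rows(lapply(seq_len(nrow(ligands)), function(i) {
        lig <- ligand_info(struct, ligands[i, ])
        d <- traj_min_dist(traj, lig$rows, srows)
        tibble(ligand = ligands$label[i], species = ligands$species[i],
               fraction_near_substrate = mean(d <= pars$sape_proximity))
      }))
    } else tibble(ligand = character(), species = character(),
                  fraction_near_substrate = double())
  })

  summary <- list(
    pipeline_version = "loxtraj-1",
    parameters = pars,
    frame_interval = dt, n_frames = n_frames(traj), run_length = rl,
    n_ligands = nrow(ligands),
    species_counts = as.list(table(ligands$species)),
    entrance_calls = setNames(as.list(entrance_calls$call),
                              entrance_calls$ligand),
    qualified_sites = qualification$site[qualification$qualified],
    site_total_occupancy = setNames(as.list(round(
      qualification$total_occupancy, 6)), qualification$site),
    n_displacement_events = nrow(competition$events),
    species_colocalization = competition$species_colocalization,
    n_competent_poses = nrow(poses),
    pose_counts_by_ligand = if (nrow(poses))
      as.list(table(poses$o2_label)) else list(),
    high_propensity_residues = profile$residue[profile$high_propensity]
  )

  out <- structure(list(config = config, ligands = ligands, traces = traces,
                        occupancy = occupancy, qualification = qualification,
                        entrance_calls = entrance_calls,
                        displacement_events = competition$events,
                        species_colocalization = competition$species_colocalization,
                        poses = poses, profile = profile,
                        sape_fraction = sape_fraction, summary = summary),
                   class = "lox_report")

  # outputs ----------------------------------------------------------------
  od <- config$output_dir
  write_tsv_plain(out$occupancy, file.path(od, "occupancy.tsv"))
  write_tsv_plain(out$qualification, file.path(od, "qualification.tsv"))
  write_tsv_plain(out$entrance_calls, file.path(od, "entrance_calls.tsv"))
  write_tsv_plain(out$displacement_events,
                  file.path(od, "displacement_events.tsv"))
  write_tsv_plain(out$poses, file.path(od, "poses.tsv"))
  write_tsv_plain(out$profile, file.path(od, "coordination_profile.tsv"))
  write_tsv_plain(out$sape_fraction, file.path(od, "substrate_proximity.tsv"))
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(od, "run.log"))
  invisible(out)
}

#' @export
print.lox_report <- function(x, ...) {
  s <- x$summary
  cat("<lox_report> ", s$n_ligands, " ligands over ", s$n_frames,
      " frames (", s$run_length, " ns)\n", sep = "")
  cat("  qualified sites: ",
      paste(s$qualified_sites, collapse = ", "), "\n", sep = "")
  cat("  displacement events: ", s$n_displacement_events,
      "; competent poses: ", s$n_competent_poses, "\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `lox_report`.
#' @param ... Unused.
#' @export
tidy.lox_report <- function(x, ...) {
  left_join(x$qualification,
            x$occupancy %>% group_by(.data$site) %>%
              summarise(n_visits = n(), .groups = "drop"),
            by = "site") %>%
    mutate(n_visits = ifelse(is.na(.data$n_visits), 0L, .data$n_visits))
}

#' @rdname run_pipeline
#' @export
glance.lox_report <- function(x, ...) {
  s <- x$summary
  tibble(n_ligands = s$n_ligands, n_frames = s$n_frames,
         run_length = s$run_length,
         n_qualified_sites = length(s$qualified_sites),
         n_displacement_events = s$n_displacement_events,
         n_competent_poses = s$n_competent_poses,
         species_colocalization = s$species_colocalization)
}

#' Compare two pipeline summaries
#'
#' Side-by-side differences between two runs (e.g. with and without a
#' binding partner): per-site total occupancy, per-species catalytic
#' access counts, and the species co-localization fraction.
#'
#' @param summary_a,summary_b Summary lists from `lox_report$summary`, or
#'   paths to `summary.json` files.
#' @return Tibble `quantity`, `key`, `value_a`, `value_b`, `difference`.
#' @export
compare_runs <- function(summary_a, summary_b) {
  rd <- function(s) if (is.character(s)) jsonlite::read_json(s,
                                                             simplifyVector = FALSE) else s
  a <- rd(summary_a); b <- rd(summary_b)
  if (!identical(a$pipeline_version, b$pipeline_version)) {
    abort("summaries come from different pipeline versions")
  }
  pa <- lapply(a$parameters, as.numeric); pb <- lapply(b$parameters, as.numeric)
  if (!identical(pa[order(names(pa))], pb[order(names(pb))])) {
    abort("summaries were produced with different parameter blocks")
  }
  rows <- list()
  sites <- union(names(a$site_total_occupancy), names(b$site_total_occupancy))
  for (snm in sites) {
    va <- as.numeric(a$site_total_occupancy[[snm]] %||% 0)
    vb <- as.numeric(b$site_total_occupancy[[snm]] %||% 0)
    rows[[length(rows) + 1L]] <- tibble(quantity = "site_occupancy_ns",
                                        key = snm, value_a = va, value_b = vb)
  }
  # catalytic access per species: ligands not called "none"
  access <- function(s) {
    calls <- unlist(s$entrance_calls)
    sp <- ifelse(grepl("^OXY", names(calls)), "O2",
                 ifelse(grepl("^NO", names(calls)), "NO", "other"))
    tapply(calls != "none", sp, sum)
  }
  aa <- access(a); ab <- access(b)
  pick <- function(v, k) if (k %in% names(v)) as.numeric(v[[k]]) else 0
  for (sp in union(names(aa), names(ab))) {
    rows[[length(rows) + 1L]] <- tibble(
      quantity = "catalytic_access_count", key = sp,
      value_a = pick(aa, sp), value_b = pick(ab, sp))
  }
  rows[[length(rows) + 1L]] <- tibble(
    quantity = "species_colocalization", key = "O2&NO",
    value_a = as.numeric(a$species_colocalization %||% NA),
    value_b = as.numeric(b$species_colocalization %||% NA))
  out <- bind_rows(rows)
  out$value_a[is.na(out$value_a)] <- NA_real_
  mutate(out, difference = .data$value_a - .data$value_b)
}
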