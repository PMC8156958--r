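# Synthetic trajectory generator with planted ground truth.
#
# The generator is phenomenological: gas particles follow a seeded
# reflecting-wall random walk, and scripted "plants" pin a ligand near a
# named site or a target atom for stated intervals. Free-flying particles
# are kept outside a clearance shell around every protein/substrate atom,
# so planted event boundaries are exact by construction and every pipeline
# stage can be validated against machine-readable ground truth.

# ---- geometry of the bead model -------------------------------------------

# residue identities reused from the reference 15LOX-2 catalog so the same
# site names resolve against synthetic and real structures alike
SYNTH_SITES <- list(
  E1 = list(res = c("154:TYR", "155:ASN", "157:GLY", "158:TRP", "421:ILE",
                    "435:ILE", "438:PHE", "439:SER"),
            centroid = c(10, 30, 30), role = "entrance"),
  S1 = list(res = c("413:ASN", "416:ALA", "417:ARG", "374:LEU", "379:LEU"),
            centroid = c(20, 30, 30), role = "binding"),
  CAT = list(res = c("373:HIS", "378:HIS", "553:HIS", "676:ILE"),
             centroid = c(30, 30, 30), role = "catalytic"),
  S2 = list(res = c("433:ILE", "431:THR", "427:VAL", "365:PHE", "369:GLU"),
            centroid = c(30, 20, 30), role = "binding"),
  E3 = list(res = c("573:SER", "595:PRO", "599:ALA", "430:SER", "603:VAL"),
            centroid = c(30, 10, 30), role = "entrance")
)

ring_points <- function(centroid, n, radius, normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- ref - sum(ref * normal) * normal; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(normal[2] * t1[3] - normal[3] * t1[2],
          normal[3] * t1[1] - normal[1] * t1[3],
          normal[1] * t1[2] - normal[2] * t1[1])
  th <- 2 * pi * (seq_len(n) - 1) / n
  t(vapply(th, function(a) centroid + radius * (cos(a) * t1 + sin(a) * t2),
           double(3)))
}

#' Build the synthetic bead-model protein
#'
#' One C-alpha-like bead per residue, grouped into the named sites E1, S1,
#' S2, E3 (surface entrances and channel binding sites) and CAT (the
#' catalytic pocket), arranged on rings around well-separated centroids
#' inside the box; plus the catalytic iron, the substrate sn-2 carbons C13
#' and C15, and a short substrate chain.
#'
#' @param box Box lengths in Angstrom; default `c(60, 60, 60)`.
#' @param site_radius Ring radius of the site beads, Angstrom; default 2.
#' @param pocket_radius Controls substrate placement scale; must be > 0.
#' @return List of class `lox_model`: `structure`, `catalog` (site catalog
#'   tibble), `refs` ([reference_atoms()]), `centroids`.
#' @export
build_protein_model <- function(box = c(60, 60, 60), site_radius = 2,
                                pocket_radius = 2) {
  if (any(box <= 0) || site_radius <= 0 || pocket_radius <= 0) {
    abort("model geometry parameters must be positive")
  }
  scale <- box / c(60, 60, 60)
  rows <- list(); cat_rows <- list()
  aid <- 0L
  for (nm in names(SYNTH_SITES)) {
    s <- SYNTH_SITES[[nm]]
    centroid <- s$centroid * scale
    normal <- centroid - c(30, 30, 30) * scale
    if (sqrt(sum(normal^2)) < 1e-6) normal <- c(0, 0, 1)
    pts <- ring_points(centroid, length(s$res), site_radius, normal)
    for (i in seq_along(s$res)) {
      aid <- aid + 1L
      p <- strsplit(s$res[i], ":", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- tibble(
        atom_id = aid, name = "CA", element = "C", chain = "A",
        resno = as.integer(p[1]), resname = p[2],
        x = pts[i, 1], y = pts[i, 2], z = pts[i, 3]
      )
    }
  }
  centre <- c(30, 30, 30) * scale
  # catalytic iron at the pocket centre
  aid <- aid + 1L; fe_id <- aid
  rows[[length(rows) + 1L]] <- tibble(atom_id = aid, name = "FE",
                                      element = "Fe", chain = "A",
                                      resno = 700L, resname = "FE",
                                      x = centre[1], y = centre[2], z = centre[3])
  # substrate chain: C13 and C15 near the pocket plus a short tail
  sap <- rbind(
    C13 = centre + c(0.8, 0, 1.2),
    C15 = centre + c(0, 0, 1) * pocket_radius,
    C16 = centre + c(0, 0.8, 3.0),
    C17 = centre + c(0, 1.2, 4.2),
    C18 = centre + c(0, 1.6, 5.4)
  )
  sap_ids <- integer(nrow(sap))
  for (i in seq_len(nrow(sap))) {
    aid <- aid + 1L; sap_ids[i] <- aid
    rows[[length(rows) + 1L]] <- tibble(atom_id = aid,
                                        name = rownames(sap)[i],
                                        element = "C", chain = "A",
                                        resno = 690L, resname = "SAP",
                                        x = sap[i, 1], y = sap[i, 2],
                                        z = sap[i, 3])
  }
  structure_tbl <- as_structure(bind_rows(rows), title = "synthetic bead model")
  catalog <- bind_rows(lapply(names(SYNTH_SITES), function(nm) {
    s <- SYNTH_SITES[[nm]]
    keys <- vapply(s$res, function(r) {
      p <- strsplit(r, ":", fixed = TRUE)[[1]]
      res_key("A", as.integer(p[1]), p[2])
    }, character(1), USE.NAMES = FALSE)
    tibble(site = nm, role = s$role, residues = list(keys))
  }))
  centroids <- lapply(SYNTH_SITES, function(s) s$centroid * scale)
  # degenerate-geometry guard: site centroids must stay well separated
  cm <- do.call(rbind, centroids)
  dd <- as.matrix(stats::dist(cm))
  if (any(dd[upper.tri(dd)] < 2 * site_radius + 2)) {
    abort("degenerate geometry: overlapping sites")
  }
  refs <- reference_atoms(fe_id, c13_atom_id = sap_ids[1],
                          c15_atom_id = sap_ids[2],
                          substrate_atom_ids = sap_ids)
  structure(list(structure = structure_tbl, catalog = catalog, refs = refs,
                 centroids = centroids), class = "lox_model")
}

# ---- plant constructors ----------------------------------------------------

#' Plant a site dwell for one ligand
#' @param ligand Ligand label, e.g. `"NO_802"`.
#' @param site Site name (must exist in the model catalog).
#' @param start Dwell start, ns.
#' @param duration Dwell duration, ns.
#' @export
plant_dwell <- function(ligand, site, start, duration) {
  list(type = "dwell", ligand = ligand, site = site,
       start = start, duration = duration)
}

#' Plant an entrance route: entrance dwell followed by a catalytic dwell
#' @param ligand Ligand label.
#' @param entrance Entrance site name (`"E1"` or `"E3"`).
#' @param arrival Entrance-visit start, ns.
#' @param entrance_dwell Entrance-visit duration, ns; default 3.
#' @param catalytic_start Catalytic-visit start, ns.
#' @param catalytic_dwell Catalytic-visit duration, ns; default 10.
#' @export
plant_route <- function(ligand, entrance, arrival, entrance_dwell = 3,
                        catalytic_start, catalytic_dwell = 10) {
  list(type = "route", ligand = ligand, entrance = entrance,
       arrival = arrival, entrance_dwell = entrance_dwell,
       catalytic_start = catalytic_start, catalytic_dwell = catalytic_dwell)
}

#' Plant a displacement event near a target atom
#'
#' The displaced ligand holds a position near the target from `start` until
#' `exit`; the displacer arrives at `displacer_entry` (inside the displaced
#' ligand's stay) and holds until `displacer_exit`.
#' @param displaced,displacer Ligand labels.
#' @param start,exit Displaced ligand's stay, ns.
#' @param displacer_entry,displacer_exit Displacer's stay, ns.
#' @export
plant_displacement <- function(displaced, displacer, start, exit,
                               displacer_entry, displacer_exit) {
  list(type = "displacement", displaced = displaced, displacer = displacer,
       start = start, exit = exit, displacer_entry = displacer_entry,
       displacer_exit = displacer_exit)
}

#' Plant a sequence of exponentially distributed dwells
#'
#' Dwell durations are drawn (at generation time, from the seeded stream)
#' from an exponential distribution, separated by fixed free-flight gaps.
#' @param ligand Ligand label.
#' @param site Site name.
#' @param n_events Number of dwells.
#' @param mean_dwell Mean of the exponential dwell distribution, ns;
#'   default 10.
#' @param gap Free gap between dwells, ns; default 2.
#' @param start First dwell start, ns; default 2.
#' @export
plant_random_dwells <- function(ligand, site, n_events, mean_dwell = 10,
                                gap = 2, start = 2) {
  list(type = "random_dwells", ligand = ligand, site = site,
       n_events = n_events, mean_dwell = mean_dwell, gap = gap,
       start = start)
}

# ---- spec ------------------------------------------------------------------

#' Specification of a synthetic gas-diffusion system
#'
#' Defaults mirror the study conditions the package is designed around:
#' 150 ns runs saved at 0.1 ns/frame, with O2 and NO at a 1:1 ratio of
#' five molecules each (presets `"1:3"` and `"3:1"` scale the minority
#' species to five).
#'
#' @param seed Mandatory RNG seed (integer).
#' @param run_length Run length, ns; default 150.
#' @param frame_interval Saved-frame interval, ns; default 0.1.
#' @param box Box lengths, Angstrom; default `c(60, 60, 60)`.
#' @param ratio `"1:1"`, `"1:3"` or `"3:1"`; sets `n_o2`/`n_no` unless they
#'   are given explicitly.
#' @param n_o2,n_no Species counts (override `ratio`).
#' @param plants List of plant specs ([plant_dwell()], [plant_route()],
#'   [plant_displacement()], [plant_random_dwells()]).
#' @param step_sd Free-flight random-walk step standard deviation,
#'   Angstrom/frame; default 1.5.
#' @param keep_out Free-flight clearance from protein/substrate atoms,
#'   Angstrom; default 10.
#' @param bond_length Rigid diatomic bond length, Angstrom; default 1.2.
#' @param jitter Optional uniform positional noise amplitude applied to gas
#'   atoms (Angstrom, per coordinate); default 0 (none).
#' @param periodic Use a periodic box (minimum-image distances) instead of
#'   reflecting walls; default `FALSE`.
#' @return List of class `lox_synthspec`.
#' @export
synthetic_spec <- function(seed, run_length = 150, frame_interval = 0.1,
                           box = c(60, 60, 60), ratio = "1:1",
                           n_o2 = NULL, n_no = NULL, plants = list(),
                           step_sd = 1.5, keep_out = 10, bond_length = 1.2,
                           jitter = 0, periodic = FALSE) {
  if (missing(seed)) abort("seed is mandatory")
  counts <- switch(ratio, "1:1" = c(5, 5), "1:3" = c(5, 15),
                   "3:1" = c(15, 5), abort("ratio must be 1:1, 1:3 or 3:1"))
  if (is.null(n_o2)) n_o2 <- counts[1]
  if (is.null(n_no)) n_no <- counts[2]
  if (n_o2 < 0 || n_no < 0) abort("species counts must be >= 0")
  nf <- run_length / frame_interval
  if (abs(nf - round(nf)) > 1e-9) {
    abort("run_length must be an integer number of frame intervals")
  }
  structure(list(seed = as.integer(seed), run_length = run_length,
                 frame_interval = frame_interval, box = box,
                 n_o2 = n_o2, n_no = n_no, plants = plants,
                 step_sd = step_sd, keep_out = keep_out,
                 bond_length = bond_length, jitter = jitter,
                 periodic = periodic),
            class = "lox_synthspec")
}

# sample a random unit 3-vector from the current RNG stream
runit3 <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# expand the plant list into per-ligand anchored segments (frames, site or
# target), drawing any random dwell durations from the seeded stream
expand_plants <- function(plants, dt, nf) {
  segs <- list()
  add <- function(lig, kind, anchor, f0, f1) {
    segs[[length(segs) + 1L]] <<- list(ligand = lig, kind = kind,
                                       anchor = anchor, f0 = f0, f1 = f1)
  }
  to_frames <- function(t0, dur) {
    f0 <- as.integer(round(t0 / dt)); f1 <- as.integer(round((t0 + dur) / dt)) - 1L
    if (f1 < f0) abort("plant with non-positive duration")
    if (f0 < 0L || f1 > nf - 1L) abort("plant outside the run")
    c(f0, f1)
  }
  truth_dwells <- list(); truth_entr <- list(); truth_disp <- list()
  for (p in plants) {
    if (p$type == "dwell") {
      fr <- to_frames(p$start, p$duration)
      add(p$ligand, "site", p$site, fr[1], fr[2])
      truth_dwells[[length(truth_dwells) + 1L]] <-
        tibble(ligand = p$ligand, site = p$site,
               start_frame = fr[1], end_frame = fr[2])
    } else if (p$type == "route") {
      fe <- to_frames(p$arrival, p$entrance_dwell)
      fc <- to_frames(p$catalytic_start, p$catalytic_dwell)
      if (fc[1] <= fe[2]) abort("route catalytic visit must follow the entrance visit")
      add(p$ligand, "site", p$entrance, fe[1], fe[2])
      add(p$ligand, "site", "CAT", fc[1], fc[2])
      truth_dwells[[length(truth_dwells) + 1L]] <-
        tibble(ligand = p$ligand, site = p$entrance,
               start_frame = fe[1], end_frame = fe[2])
      truth_dwells[[length(truth_dwells) + 1L]] <-
        tibble(ligand = p$ligand, site = "CAT",
               start_frame = fc[1], end_frame = fc[2])
      truth_entr[[length(truth_entr) + 1L]] <-
        tibble(ligand = p$ligand, entrance = p$entrance,
               first_entrance_time = fe[1] * dt,
               first_catalytic_time = fc[1] * dt)
    } else if (p$type == "displacement") {
      fa <- to_frames(p$start, p$exit - p$start)
      fb <- to_frames(p$displacer_entry, p$displacer_exit - p$displacer_entry)
      if (fb[1] < fa[1] || fb[1] > fa[2] + 1L) {
        abort("displacer must arrive during the displaced ligand's stay")
      }
      add(p$displaced, "target", "C15", fa[1], fa[2])
      add(p$displacer, "target", "C15", fb[1], fb[2])
      truth_disp[[length(truth_disp) + 1L]] <-
        tibble(displaced = p$displaced, displacer = p$displacer,
               overlap_start = fb[1] * dt,
               displacement_time = (fa[2] + 1L) * dt)
    } else if (p$type == "random_dwells") {
      t0 <- p$start
      durs <- rexp(p$n_events, rate = 1 / p$mean_dwell)
      durs <- pmax(durs, dt)  # at least one frame
      for (d in durs) {
        d <- round(d / dt) * dt
        if (d < dt) d <- dt
        if (t0 + d > nf * dt) abort("random dwell plan exceeds the run length")
        fr <- to_frames(t0, d)
        add(p$ligand, "site", p$site, fr[1], fr[2])
        truth_dwells[[length(truth_dwells) + 1L]] <-
          tibble(ligand = p$ligand, site = p$site,
                 start_frame = fr[1], end_frame = fr[2])
        t0 <- t0 + d + p$gap
      }
    } else {
      abort(paste0("unknown plant type: ", p$type))
    }
  }
  # feasibility: segments of one ligand must not overlap, and same-site
  # dwells must be separated by more than the default merge gap
  by_lig <- split(segs, vapply(segs, `[[`, character(1), "ligand"))
  for (lig in names(by_lig)) {
    ss <- by_lig[[lig]]
    ord <- order(vapply(ss, `[[`, numeric(1), "f0"))
    ss <- ss[ord]
    if (length(ss) > 1L) {
      for (i in 2:length(ss)) {
        gap <- ss[[i]]$f0 - ss[[i - 1L]]$f1 - 1L
        if (gap < 0L) {
          abort(paste0("infeasible script: overlapping plants for ", lig))
        }
        if (ss[[i]]$anchor == ss[[i - 1L]]$anchor && gap * dt <= 1) {
          abort(paste0("infeasible script: plants for ", lig, " at ",
                       ss[[i]]$anchor, " are too close to stay distinct"))
        }
      }
    }
  }
  list(
    segments = segs,
    dwells = if (length(truth_dwells)) bind_rows(truth_dwells) else
      tibble(ligand = character(), site = character(),
             start_frame = integer(), end_frame = integer()),
    entrances = if (length(truth_entr)) bind_rows(truth_entr) else
      tibble(ligand = character(), entrance = character(),
             first_entrance_time = double(), first_catalytic_time = double()),
    displacements = if (length(truth_disp)) bind_rows(truth_disp) else
      tibble(displaced = character(), displacer = character(),
             overlap_start = double(), displacement_time = double())
  )
}

#' Simulate a synthetic gas trajectory with ground truth
#'
#' Gas particles (rigid diatomics) follow a seeded random walk with
#' reflecting walls, staying outside a clearance shell around the protein
#' model; scripted plants pin ligands near sites or near the substrate
#' carbon C15 for stated intervals. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `lox_synth`: `traj` (`lox_trajectory`), `truth`
#'   (class `lox_truth`: tibbles `dwells`, `entrances`, `displacements`,
#'   `pose_frames`), `catalog`, `refs`, `model`.
#' @export
simulate_gas_trajectory <- function(spec) {
  stopifnot(inherits(spec, "lox_synthspec"))
  set.seed(spec$seed)
  dt <- spec$frame_interval
  nf <- as.integer(round(spec$run_length / dt))
  model <- build_protein_model(box = spec$box)
  prot <- model$structure
  P <- as.matrix(prot[, c("x", "y", "z")])
  centroids <- model$centroids
  c15 <- unlist(prot[prot$name == "C15", c("x", "y", "z")], use.names = FALSE)

  # gas atoms appended after the protein: OXY 701.. (O1,O2), NO 801.. (N,O)
  gas_rows <- list()
  aid <- max(prot$atom_id)
  labels <- character(0); species <- character(0)
  mk_gas <- function(resname, resno, elements, names_) {
    for (i in 1:2) {
      aid <<- aid + 1L
      gas_rows[[length(gas_rows) + 1L]] <<- tibble(
        atom_id = aid, name = names_[i], element = elements[i], chain = "X",
        resno = resno, resname = resname, x = 0, y = 0, z = 0)
    }
  }
  if (spec$n_o2 > 0) for (i in seq_len(spec$n_o2)) {
    mk_gas("OXY", 700L + i, c("O", "O"), c("O1", "O2"))
    labels <- c(labels, paste0("OXY_", 700L + i)); species <- c(species, "O2")
  }
  if (spec$n_no > 0) for (i in seq_len(spec$n_no)) {
    mk_gas("NO", 800L + i, c("N", "O"), c("N", "O"))
    labels <- c(labels, paste0("NO_", 800L + i)); species <- c(species, "NO")
  }
  full <- as_structure(bind_rows(list(as_tibble(prot)), gas_rows),
                       title = "synthetic system")
  n_lig <- length(labels)
  plan <- expand_plants(spec$plants, dt, nf)
  bad <- setdiff(vapply(plan$segments, `[[`, character(1), "ligand"), labels)
  if (length(bad)) {
    abort(paste0("plants reference unknown ligand(s): ",
                 paste(unique(bad), collapse = ", ")))
  }

  # per-ligand per-frame anchor table: "" = free, else "site:NAME" / "target"
  anchor <- matrix("", nrow = nf, ncol = n_lig, dimnames = list(NULL, labels))
  for (sg in plan$segments) {
    anchor[(sg$f0:sg$f1) + 1L, sg$ligand] <-
      if (sg$kind == "site") paste0("site:", sg$anchor) else "target"
  }

  lo <- rep(1, 3); hi <- spec$box - 1
  clear2 <- spec$keep_out^2
  free_point <- function() {
    repeat {
      p <- lo + runif(3) * (hi - lo)
      if (min(rowSums((P - matrix(p, nrow(P), 3, byrow = TRUE))^2)) >= clear2) {
        return(p)
      }
    }
  }
  co <- array(0, c(nf, nrow(full), 3))
  for (f in seq_len(nf)) co[f, seq_len(nrow(prot)), ] <- P

  for (li in seq_len(n_lig)) {
    rows <- nrow(prot) + 2L * (li - 1L) + 1:2
    pos <- NULL; prev_free <- FALSE
    for (f in seq_len(nf)) {
      a <- anchor[f, li]
      if (a == "") {
        if (!prev_free || is.null(pos)) {
          pos <- free_point()
        } else {
          for (try in 1:20) {
            cand <- pos + rnorm(3, sd = spec$step_sd)
            cand <- pmin(pmax(cand, lo), hi)  # reflecting walls (clamped)
            if (min(rowSums((P - matrix(cand, nrow(P), 3,
                                        byrow = TRUE))^2)) >= clear2) {
              pos <- cand; break
            }
          }
        }
        prev_free <- TRUE
      } else if (a == "target") {
        r <- runif(1, 2.5, 5.5)
        pos <- c15 + r * runit3()
        prev_free <- FALSE
      } else {
        site <- sub("^site:", "", a)
        cc <- centroids[[site]]
        if (is.null(cc)) abort(paste0("unknown site in plant: ", site))
        pos <- cc + 0.5 * runif(1)^(1 / 3) * runit3()
        prev_free <- FALSE
      }
      u <- runit3() * spec$bond_length / 2
      co[f, rows[1], ] <- pos + u
      co[f, rows[2], ] <- pos - u
    }
  }
  if (spec$jitter > 0) {
    g <- nrow(prot) + seq_len(2L * n_lig)
    co[, g, ] <- co[, g, ] + runif(length(co[, g, ]), -spec$jitter, spec$jitter)
  }
  traj <- as_trajectory(full, co, dt, box = if (spec$periodic) spec$box else NULL)

  # planted competent-pose frames: O2 ligands anchored in the pocket
  pose <- list()
  for (li in which(species == "O2")) {
    in_pocket <- anchor[, li] == "target" | anchor[, li] == "site:CAT"
    if (any(in_pocket)) {
      pose[[length(pose) + 1L]] <- tibble(ligand = labels[li],
                                          frame = which(in_pocket) - 1L)
    }
  }
  pose_frames <- if (length(pose)) bind_rows(pose) else
    tibble(ligand = character(), frame = integer())

  dw <- plan$dwells
  if (nrow(dw)) {
    dw$start_time <- dw$start_frame * dt
    dw$end_time <- (dw$end_frame + 1L) * dt
    dw$duration <- dw$end_time - dw$start_time
  } else {
    dw$start_time <- double(); dw$end_time <- double(); dw$duration <- double()
  }
  truth <- structure(list(dwells = dw, entrances = plan$entrances,
                          displacements = plan$displacements,
                          pose_frames = pose_frames,
                          labels = labels, species = species),
                     class = "lox_truth")
  structure(list(traj = traj, truth = truth, catalog = model$catalog,
                 refs = model$refs, model = model, spec = spec),
            class = "lox_synth")
}

#' The default synthetic study system
#'
#' A 150 ns, 0.1 ns/frame box with five O2 and five NO molecules around the
#' bead-model protein, planting: a 70 ns S1 dwell and a 35 ns S2 dwell
#' (the residence scales reported for the two channel binding sites); an
#' E1 entry route and an E3 entry route reaching the catalytic site; and
#' one pocket competition in which an O2 holds a position near C15 from
#' 43 ns, an NO arrives at 74 ns, and the O2 leaves at 145 ns.
#'
#' @param seed RNG seed.
#' @param jitter Optional positional noise amplitude, Angstrom; default 0.
#' @return A [synthetic_spec()].
#' @export
default_bundle_spec <- function(seed, jitter = 0) {
  synthetic_spec(
    seed = seed, run_length = 150, frame_interval = 0.1, ratio = "1:1",
    jitter = jitter,
    plants = list(
      plant_route("OXY_701", "E1", arrival = 37, entrance_dwell = 3,
                  catalytic_start = 45, catalytic_dwell = 10),
      plant_route("NO_801", "E3", arrival = 10, entrance_dwell = 3,
                  catalytic_start = 20, catalytic_dwell = 8),
      plant_dwell("NO_802", "S1", start = 20, duration = 70),
      plant_dwell("OXY_702", "S2", start = 50, duration = 35),
      plant_dwell("NO_803", "S1", start = 100, duration = 12),
      plant_displacement("OXY_705", "NO_805", start = 43, exit = 145,
                         displacer_entry = 74, displacer_exit = 150)
    )
  )
}

#' Study system with a chain of planted displacement events
#'
#' One O2 and one NO alternate at the pocket target in scripted episodes:
#' per 11 ns episode the O2 holds a position near C15 for 5.5 ns, the NO
#' arrives 3 ns in and remains past the O2's departure, producing exactly
#' one displacement event per episode. Used to measure detection precision
#' and recall against a known event count, optionally under positional
#' jitter.
#'
#' @param seed RNG seed.
#' @param n_events Number of scripted episodes; default 100.
#' @param jitter Uniform positional noise amplitude, Angstrom; default 0.
#' @return A [synthetic_spec()] whose truth carries `n_events` displacement
#'   events.
#' @export
displacement_chain_spec <- function(seed, n_events = 100, jitter = 0) {
  plants <- lapply(seq_len(n_events), function(k) {
    t0 <- 2 + (k - 1) * 11
    plant_displacement("OXY_701", "NO_801", start = t0, exit = t0 + 5.5,
                       displacer_entry = t0 + 3, displacer_exit = t0 + 8.5)
  })
  synthetic_spec(seed = seed, run_length = n_events * 11 + 8,
                 frame_interval = 0.1, n_o2 = 1, n_no = 1,
                 plants = plants, jitter = jitter)
}

#' Study system with exponentially distributed site dwells
#'
#' Every gas ligand repeatedly dwells at binding site S1 with
#' exponentially distributed durations (drawn at generation time from the
#' seeded stream) separated by fixed free-flight gaps, giving
#' `n_ligands * events_per_ligand` planted dwell events for residence-time
#' estimator validation.
#'
#' @param seed RNG seed.
#' @param n_ligands Number of gas ligands (split between O2 and NO);
#'   default 10.
#' @param events_per_ligand Dwells per ligand; default 60.
#' @param mean_dwell Exponential mean dwell, ns; default 10.
#' @param gap Free gap between dwells, ns; default 2.
#' @param run_length Run length, ns; default 1100.
#' @return A [synthetic_spec()].
#' @export
dwell_recovery_spec <- function(seed, n_ligands = 10, events_per_ligand = 60,
                                mean_dwell = 10, gap = 2, run_length = 1100) {
  n_o2 <- ceiling(n_ligands / 2); n_no <- n_ligands - n_o2
  labels <- c(paste0("OXY_", 700 + seq_len(n_o2)),
              if (n_no > 0) paste0("NO_", 800 + seq_len(n_no)))
  plants <- lapply(labels, function(lb)
    plant_random_dwells(lb, "S1", events_per_ligand,
                        mean_dwell = mean_dwell, gap = gap, start = 2))
  synthetic_spec(seed = seed, run_length = run_length, frame_interval = 0.1,
                 n_o2 = n_o2, n_no = n_no, plants = plants)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the structure (PDB and fixture-text), the trajectory (fixture-text
#' and DCD), the site catalog and reference-atom configs (YAML), and the
#' ground-truth tables (TSV).
#'
#' @param synth A `lox_synth` from [simulate_gas_trajectory()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(synth, dir) {
  stopifnot(inherits(synth, "lox_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  f <- list(
    structure_pdb = file.path(dir, "structure.pdb"),
    structure_txt = file.path(dir, "structure.txt"),
    trajectory_txt = file.path(dir, "trajectory.txt"),
    trajectory_dcd = file.path(dir, "trajectory.dcd"),
    sites = file.path(dir, "sites.yaml"),
    refs = file.path(dir, "refatoms.yaml"),
    truth_dwells = file.path(dir, "truth_dwells.tsv"),
    truth_entrances = file.path(dir, "truth_entrances.tsv"),
    truth_displacements = file.path(dir, "truth_displacements.tsv"),
    truth_pose_frames = file.path(dir, "truth_pose_frames.tsv")
  )
  write_structure_pdb(synth$traj$structure, f$structure_pdb)
  write_structure_text(synth$traj$structure, f$structure_txt)
  write_trajectory_text(synth$traj, f$trajectory_txt)
  write_trajectory_dcd(synth$traj, f$trajectory_dcd)
  write_site_catalog(synth$catalog, f$sites)
  write_reference_atoms(synth$refs, f$refs)
  write_tsv_plain(synth$truth$dwells, f$truth_dwells)
  write_tsv_plain(synth$truth$entrances, f$truth_entrances)
  write_tsv_plain(synth$truth$displacements, f$truth_displacements)
  write_tsv_plain(synth$truth$pose_frames, f$truth_pose_frames)
  invisible(f)
}

# single-header TSV writer used for every exported table
write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth bundle back from disk
#' @param dir Bundle directory.
#' @return `lox_truth`-like list of tibbles.
#' @export
read_ground_truth <- function(dir) {
  rd <- function(nm) as_tibble(utils::read.table(file.path(dir, nm),
                                                 header = TRUE, sep = "\t",
                                                 stringsAsFactors = FALSE))
  structure(list(dwells = rd("truth_dwells.tsv"),
                 entrances = rd("truth_entrances.tsv"),
                 displacements = rd("truth_displacements.tsv"),
                 pose_frames = rd("truth_pose_frames.tsv")),
            class = "lox_truth")
}
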