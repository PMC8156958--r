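---
title: "Analysing gas-ligand migration, competition and catalytic poses in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing gas-ligand migration, competition and catalytic poses in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtraj)
library(dplyr)
```

## The problem

Dioxygenases such as human 15-lipoxygenase-2 (15LOX-2) act on substrates
buried deep inside the protein, so their co-substrate — molecular oxygen —
must migrate from the solvent through surface pores and interior channels
to the catalytic iron. Nitric oxide, a radical of almost the same size and
hydrophobicity, can use the same routes and compete with O2 for space near
the oxygenation site, which is one proposed mechanism for NO•
suppression of ferroptotic lipid peroxidation. Establishing this picture
from molecular-dynamics trajectories requires a family of geometric
analyses: per-residue contact timelines, residence times at named sites,
entrance assignment along migration paths, two-species displacement events
near a target atom, and counts of "catalytically competent" geometries.
`loxtraj` implements that analysis layer as composable, tested functions,
together with a synthetic-trajectory generator that plants known events so
every stage can be validated end to end.

## Objects and conventions

* **Structure**: a tibble of atoms (`atom_id`, `name`, `element`, `chain`,
  `resno`, `resname`, `x`, `y`, `z`), coordinates in Angstrom. Residues
  are addressed by the key `"chain:resno:resname"`.
* **Trajectory**: the structure plus an `n_frames x n_atoms x 3` array.
  Frames are 0-based and the time of frame *i* is
  `i * frame_interval` ns. The frame-saving interval of production MD is
  archive metadata that cannot be recovered from coordinates, so it is a
  *required input* everywhere, never inferred; synthetic fixtures default
  to 0.1 ns/frame. All duration thresholds are expressed in ns, not frame
  counts, so analyses are invariant to the saving cadence.
* **Distances**: heavy atoms only by default (hydrogen placement is
  force-field dependent and gas-ligand packing is dominated by heavy
  atoms); the `include_hydrogens` switch restores full-atom behaviour.
  With a periodic box, minimum-image distances are used; the synthetic
  generator is non-periodic (reflecting walls) by default so distance
  semantics in tests are unambiguous.

## Boundary semantics

Two families of criteria carry deliberately different boundary rules:

* a **contact** is an atom–atom distance *strictly less than* the 3.5 Å
  cutoff, and the dual pose criterion (below) is strict at 7.5 Å;
* the **frequent-contact filter** keeps residues with cumulative contact
  time *greater than or equal to* 2.5 ns, and shell/proximity selections
  (20 Å iron shell, 7 Å substrate shell, 7.5 Å proximity series) are
  inclusive.

These choices are pinned by boundary tests at exactly 3.4/3.5/3.6 Å and
2.4/2.5 ns. Ranked outputs break ties by ascending residue number so every
result is deterministic.

## Site occupancy and binding-site qualification

A frame is *occupied* when the ligand contacts at least `min_residues`
(default 1) of the site's residues; occupied runs separated by gaps of at
most `merge_gap` (default 0.5 ns) are merged, because single-residue
grazing plus thermal flicker should not fragment what is physically one
dwell. Merged gap frames count into the interval duration; with
`merge_gap = 0` the intervals partition the occupied frame set exactly,
and that conservation property is tested.

Binding-site *qualification* is stated in the literature only as "meeting
the criteria"; this package adopts an operational rule — total occupancy
of at least `qualify_fraction` (default 0.20) of the run length — chosen
so that both canonical channel sites (occupied >70 ns and >35 ns of
150 ns runs) qualify with margin. The fraction is a visible, configurable
parameter, not a constant.

## Entrances and path traces

`trace_path()` turns per-site occupancy into a time-ordered visit list
(co-visits of overlapping sites are kept and flagged). The entrance
*call* for a ligand is the entrance whose first visit most recently
precedes its first catalytic-site contact: when several entrances were
visited, the portal physically connected to the entry event is the last
one crossed. Catalytic-site contact means contact with the catalytic
residue set or arrival within 7.5 Å of the iron, consistent with the pose
criterion. A ligand that never reaches the catalytic site is called
`none`; first visits of two entrances within one frame of each other —
or a catalytic arrival with no recorded entrance visit at all (e.g. a
ligand starting inside the pocket) — are called `ambiguous` rather than
guessed.

## Displacement events

The competition narrative ("one molecule disrupts the binding of the
other, which eventually leaves") is formalised by three parameters, all
in ns: the displaced ligand must have been within the proximity threshold
continuously for `min_pre_dwell` (default 5); the displacer must first
come within during that stay or within `max_entry_gap` (default 1) of its
end; and the displaced ligand must then stay out for `min_post_absence`
(default 5), with absence runs truncated by the end of the trajectory
counted at face value. The defaults are wide enough that the canonical
pocket competition (a ~100 ns stay, ~70 ns of overlap, terminal
departure) is detected, and narrow enough that mere succession is not.
This is an operational definition of this package, labelled as such in
reports. Proximity of a diatomic is its nearest atom, not its centroid,
matching contact semantics.

## Competent poses and coordination profiles

A *competent pose* is one (frame, O2 instance) pair with the O2 within
7.5 Å (strict) of the substrate sn-2 carbon C15 while C13 is within
7.5 Å (strict) of the catalytic iron — the geometric precondition for
hydrogen abstraction and peroxidation. Multiple O2 molecules satisfying
the criterion in the same frame count as separate poses (reported per
ligand and in aggregate), and C13/C15 are identified by configured atom
ids, never guessed from atom names in arbitrary PDB dialects.
`coordination_profile()` reports, over a frame selection that defaults to
the competent-pose frames, the fraction of frames in which each candidate
residue touches the substrate; candidates may span chains so partner
protein residues appear in the same profile.

## The synthetic generator

`simulate_gas_trajectory()` is phenomenological, not physical: acceptance
testing needs known ground truth, not realism. Its components:

* a bead protein model — one bead per residue, arranged in rings of
  radius 2 Å around five site centroids at least 8 Å apart (two surface
  entrances E1/E3, channel sites S1/S2, and the catalytic pocket CAT with
  iron, C13/C15 and a short substrate chain), reusing the reference
  residue numbering so the shipped site catalog resolves against both
  synthetic and real structures;
* rigid diatomic gas particles (1.2 Å bond) doing a seeded random walk
  (step sd 1.5 Å/frame) inside reflecting walls, kept at least 10 Å away
  from every protein/substrate bead while "free";
* scripted plants that pin a ligand near a site centroid (within 0.5 Å)
  or at 2.5–5.5 Å from the C15 target for stated intervals.

The clearance zone and the planting radii are chosen so that planted
events are recovered *exactly*: an anchored ligand is always in contact
with its site (worst-case nearest-atom distance ≈ 2.6 Å < 3.5 Å), a free
ligand can never be (≥ 10 Å), and the pocket plant stays ≥ 1 Å clear of
the 7.5 Å proximity threshold so that the optional ±0.5 Å uniform jitter
(used for noise-robustness checks) can neither delete nor create a
detection — the robustness margin is part of the planting geometry, by
design. Infeasible scripts (overlapping plants, same-site plants closer
than the merge gap, plants outside the run) are rejected at expansion
time. Identical spec + seed gives bit-identical trajectories and bundles.

Default study conditions mirror the system the package is designed
around: 150 ns runs saved at 0.1 ns/frame, five O2 and five NO (ratio
presets 1:3 and 3:1 keep five of the minority species), a 70 ns S1 dwell
and a 35 ns S2 dwell, one E1 and one E3 entry route, and one scripted
pocket competition (hold from 43 ns, rival arrival at 74 ns, departure at
145 ns).

What the generator does **not** emulate: continuous diffusion paths into
the sites (transitions teleport, there is no channel geometry), solvent,
energetics, correlated protein motions, or conformational change.
Passing the plant-recovery suite therefore demonstrates that the analysis
layer is correct on trajectories whose truth is known — not that real
trajectories are this clean; on real data, contact flicker and partial
site entry make `merge_gap` and `min_residues` genuinely load-bearing.

Validation problem sizes are the package's own choices: oracle
equivalence on randomized fixtures of a few hundred atoms; displacement
precision/recall on a 100-episode scripted chain (one event per 11 ns
episode over ~1100 ns); residence-time recovery on 600 exponential dwells
of mean 10 ns across ten ligands (sampling error of the mean ≈ 0.4 ns).

## Mass arithmetic

The `masscalc` utilities build diacyl-PE formulas constructively
(glycerophosphoethanolamine backbone C5H14NO6P + two acyls − 2 H2O) with
modification deltas: hydroperoxy +O2, hydroxy +O, and nitroso +NO −H —
the bookkeeping of NO• coupling to a carbon-centered lipid radical.
Monoisotopic masses come from a shipped IUPAC table and [M−H]⁻ subtracts
one proton mass (1.00727646688 Da). The computed nitroso adduct of
PE(18:0/20:4) is C43H77N2O9P with [M−H]⁻ ≈ 795.529; observed instrument
values for such species can differ by low tens of ppm and are treated as
observations, not oracles. Reported precision is four decimals;
comparisons always use absolute tolerances.

## Known limitations

* Sites are residue sets; there is no geometric tunnel computation, so a
  ligand "in a channel" but out of contact with the defining residues is
  invisible between sites.
* XTC trajectories are not read; supported inputs are PDB + DCD or the
  documented plain-text fixture format (DCD is written in single
  precision; the text format is the lossless interchange).
* Displacement detection is pairwise and geometric; it does not model
  three-body exchanges or energetic competition.
* The S0 "first recognition site" is mapped onto the E1 residue set with
  role `binding` as a working definition, flagged in the shipped catalog.
* `qualify_binding_site()` treats the summed occupancy of all ligands at
  a site as the qualifying quantity; per-ligand qualification is
  available by filtering the occupancy table first.

## A worked mini-analysis

```{r example, eval = FALSE}
synth <- simulate_gas_trajectory(default_bundle_spec(seed = 1))
lig <- find_ligands(synth$traj$structure)

# where did NO_802 dwell?
trace_path(synth$traj, lig[lig$label == "NO_802", ], synth$catalog)

# who displaced whom near C15?
series <- lapply(seq_len(nrow(lig)), function(i)
  proximity_series(synth$traj, lig[i, ], synth$refs$c15, threshold = 7.5))
detect_displacements(series, frame_interval = 0.1)

# full pipeline on a written bundle
dir <- tempfile()
files <- write_fixture_bundle(synth, dir)
cfg <- run_config(files$structure_pdb, files$trajectory_txt, files$sites,
                  files$refs, frame_interval = 0.1,
                  output_dir = file.path(dir, "out"))
report <- run_pipeline(cfg)
glance(report)
```
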