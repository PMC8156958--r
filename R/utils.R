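# Internal geometry and bookkeeping helpers shared across modules.

# Residue keys are strings "chain:resno:resname", e.g. "A:373:HIS".
res_key <- function(chain, resno, resname) {
  paste(chain, resno, resname, sep = ":")
}

# Split residue keys back into a tibble of components.
split_res_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    abort(paste0("malformed residue key(s): ", paste(keys[bad], collapse = ", ")))
  }
  tibble(
    chain = vapply(parts, `[[`, character(1), 1L),
    resno = as.integer(vapply(parts, `[[`, character(1), 2L)),
    resname = vapply(parts, `[[`, character(1), 3L)
  )
}

# Residue number extracted from a key (for deterministic tie-breaking).
res_key_number <- function(keys) {
  split_res_key(keys)$resno
}

# Minimum-image component-wise difference for an orthorhombic box.
# `d` is an n x 3 matrix of raw differences; `box` a length-3 vector or NULL.
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

# Squared distances between every row of A (n x 3) and every row of B (m x 3),
# with optional minimum-image convention. Returns n x m matrix.
cross_dist2 <- function(A, B, box = NULL) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  out
}

# Minimum distance between atom sets idx_a and idx_b for every frame of a
# trajectory. Vectorised over frames: loops over the (small) atom-pair grid.
traj_min_dist <- function(traj, idx_a, idx_b) {
  co <- traj$coords
  box <- traj$box
  nf <- dim(co)[1]
  best <- rep(Inf, nf)
  for (i in idx_a) {
    for (j in idx_b) {
      d2 <- rep(0, nf)
      for (k in 1:3) {
        d <- co[, i, k] - co[, j, k]
        if (!is.null(box)) d <- d - box[k] * round(d / box[k])
        d2 <- d2 + d * d
      }
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

# TRUE-run extraction from a logical vector: tibble(start, end), 0-based frames.
bool_runs <- function(x) {
  x <- as.logical(x)
  if (!length(x) || !any(x)) {
    return(tibble(start = integer(), end = integer()))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

# Merge runs separated by gaps of at most `max_gap_frames` frames.
merge_runs <- function(runs, max_gap_frames) {
  if (nrow(runs) <= 1L || max_gap_frames <= 0L) return(runs)
  runs <- dplyr::arrange(runs, .data$start)
  out_start <- runs$start[1]; out_end <- runs$end[1]
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - out_end - 1L
    if (gap <= max_gap_frames) {
      out_end <- max(out_end, runs$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- runs$start[i]; out_end <- runs$end[i]
    }
  }
  tibble(start = c(starts, out_start), end = c(ends, out_end))
}

# Heavy-atom row indices of a structure for a set of residue keys.
# `include_hydrogens` switches the documented H-handling behaviour.
residue_atom_rows <- function(structure, residue_keys, include_hydrogens = FALSE) {
  keys <- res_key(structure$chain, structure$resno, structure$resname)
  rows <- which(keys %in% residue_keys)
  if (!include_hydrogens) {
    rows <- rows[structure$element[rows] != "H"]
  }
  rows
}

# Row indices for a vector of atom_ids (errors on missing ids).
atom_rows <- function(structure, atom_ids) {
  rows <- match(atom_ids, structure$atom_id)
  if (anyNA(rows)) {
    abort(paste0("atom id(s) not present in structure: ",
                 paste(atom_ids[is.na(rows)], collapse = ", ")))
  }
  rows
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0(what, " must be a single positive number"))
  }
  invisible(x)
}

# Three-letter residue names for the one-letter codes used in site catalogs.
AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
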