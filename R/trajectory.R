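#' Construct a trajectory object
#'
#' A trajectory couples a structure's atom table with per-frame coordinates.
#' Frames are 0-based; the time of frame `i` is `i * frame_interval`
#' nanoseconds. Coordinates are Angstrom.
#'
#' @param structure A `lox_structure`.
#' @param coords Array `n_frames x n_atoms x 3`.
#' @param frame_interval Time between saved frames, ns (> 0).
#' @param box Optional periodic box lengths (length-3, Angstrom); `NULL`
#'   means non-periodic.
#' @return An object of class `lox_trajectory`.
#' @export
as_trajectory <- function(structure, coords, frame_interval, box = NULL) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  if (dim(coords)[1] < 1L) abort("trajectory must have at least one frame")
  if (dim(coords)[2] != nrow(structure)) {
    abort(paste0("atom-count mismatch: trajectory has ", dim(coords)[2],
                 " atoms, structure has ", nrow(structure)))
  }
  if (!is.null(box) && (length(box) != 3L || any(box <= 0))) {
    abort("box must be three positive lengths")
  }
  structure(
    list(structure = structure, coords = coords,
         frame_interval = frame_interval, box = box),
    class = "lox_trajectory"
  )
}

#' @export
print.lox_trajectory <- function(x, ...) {
  cat("<lox_trajectory> ", n_frames(x), " frames x ", dim(x$coords)[2],
      " atoms, dt = ", x$frame_interval, " ns (",
      format(run_length(x)), " ns total), ",
      if (is.null(x$box)) "non-periodic" else "periodic", "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `lox_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Total simulated time covered by a trajectory (ns)
#'
#' Defined as `n_frames * frame_interval`, i.e. each saved frame represents
#' one frame interval of simulated time.
#' @param traj A `lox_trajectory`.
#' @export
run_length <- function(traj) n_frames(traj) * traj$frame_interval

#' Frame times in nanoseconds (0-based frames)
#' @param traj A `lox_trajectory`.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) * traj$frame_interval

#' Coordinates of one frame
#' @param traj A `lox_trajectory`.
#' @param frame 0-based frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 0 || frame >= n_frames(traj)) {
    abort(paste0("frame ", frame, " out of range [0, ", n_frames(traj) - 1, "]"))
  }
  m <- traj$coords[frame + 1L, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Load a trajectory from DCD or the plain-text fixture format
#'
#' The fixture-text format has a header line
#' `n_atoms n_frames frame_interval_ns` followed, for each frame, by
#' `n_atoms` lines of `atom_id x y z`. DCD files are read with
#' \pkg{bio3d} and require `frame_interval` to be given (DCD headers do not
#' carry a trustworthy save interval).
#'
#' @param path File path.
#' @param structure The matching `lox_structure` (atom counts must agree).
#' @param frame_interval ns per frame; mandatory for DCD, for text it
#'   defaults to the header value.
#' @param format `"auto"`, `"dcd"` or `"txt"`.
#' @param box Optional periodic box lengths.
#' @return A `lox_trajectory`.
#' @export
load_trajectory <- function(path, structure, frame_interval = NULL,
                            format = c("auto", "dcd", "txt"), box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "txt"
  }
  n_atoms <- nrow(structure)
  if (format == "dcd") {
    if (is.null(frame_interval)) {
      abort("frame_interval is required for DCD trajectories")
    }
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nf <- nrow(xyz)
    if (ncol(xyz) != 3L * n_atoms) {
      abort(paste0("atom-count mismatch: DCD has ", ncol(xyz) / 3,
                   " atoms, structure has ", n_atoms))
    }
    co <- array(0, c(nf, n_atoms, 3))
    for (k in 1:3) co[, , k] <- xyz[, seq(k, 3 * n_atoms, by = 3), drop = FALSE]
    as_trajectory(structure, co, frame_interval, box = box)
  } else {
    header <- scan(path, what = double(), nlines = 1, quiet = TRUE)
    if (length(header) != 3L) {
      abort(paste0("malformed trajectory header in ", path,
                   " (line 1): expected 'n_atoms n_frames frame_interval_ns'"))
    }
    na <- as.integer(header[1]); nf <- as.integer(header[2]); dt <- header[3]
    if (na != n_atoms) {
      abort(paste0("atom-count mismatch: trajectory has ", na,
                   " atoms, structure has ", n_atoms))
    }
    if (nf < 1L) abort("trajectory has zero frames")
    if (is.null(frame_interval)) frame_interval <- dt
    dat <- scan(path, what = double(), skip = 1, quiet = TRUE)
    if (length(dat) != na * nf * 4L) {
      abort(paste0("malformed trajectory body in ", path, ": expected ",
                   na * nf, " records of 'atom_id x y z'"))
    }
    m <- matrix(dat, ncol = 4, byrow = TRUE)
    ids_first <- m[seq_len(na), 1]
    ord <- match(structure$atom_id, ids_first)
    if (anyNA(ord)) abort("trajectory atom ids do not match the structure")
    co <- array(0, c(nf, na, 3))
    for (f in seq_len(nf)) {
      block <- m[(f - 1L) * na + seq_len(na), , drop = FALSE]
      co[f, , ] <- block[ord, 2:4, drop = FALSE]
    }
    as_trajectory(structure, co, frame_interval, box = box)
  }
}

#' Write a trajectory in the plain-text fixture format
#' @param traj A `lox_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_text <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  writeLines(sprintf("%d %d %.10g", na, nf, traj$frame_interval), con)
  ids <- traj$structure$atom_id
  for (f in seq_len(nf)) {
    writeLines(sprintf("%d %.6f %.6f %.6f", ids,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as DCD
#'
#' Emits an X-PLOR style single-precision DCD (readable by common MD
#' viewers and by `bio3d::read.dcd`). Coordinates are stored as 32-bit
#' floats, so round-trips are exact only to single precision; the
#' fixture-text format is the lossless interchange format.
#'
#' @param traj A `lox_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  nf <- n_frames(traj); na <- dim(traj$coords)[2]
  con <- file(path, open = "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record framing: length, payload, length
    raw_payload <- writer()
    writeBin(length(raw_payload), con, size = 4, endian = "little")
    writeBin(raw_payload, con)
    writeBin(length(raw_payload), con, size = 4, endian = "little")
  }
  rec(function() {
    icntrl <- integer(20)
    icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
    c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4, endian = "little"))
  })
  rec(function() {
    title <- sprintf("%-80s", "loxtraj synthetic trajectory")
    c(writeBin(1L, raw(), size = 4, endian = "little"),
      charToRaw(substr(title, 1, 80)))
  })
  rec(function() writeBin(as.integer(na), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      rec(function() writeBin(as.numeric(traj$coords[f, , k]), raw(),
                              size = 4, endian = "little"))
    }
  }
  invisible(path)
}
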