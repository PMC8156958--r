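#' Construct a structure atom table
#'
#' A structure is a tibble with one row per atom and columns `atom_id`,
#' `name`, `element`, `chain`, `resno`, `resname`, `x`, `y`, `z`
#' (coordinates in Angstrom). Atom order is meaningful: trajectory frames
#' index atoms by their row position.
#'
#' @param atoms Data frame with the columns above.
#' @param title Optional title string carried as an attribute.
#' @return A tibble of class `lox_structure`.
#' @export
as_structure <- function(atoms, title = "") {
  need <- c("atom_id", "name", "element", "chain", "resno", "resname",
            "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("structure is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)[, need]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$resno <- as.integer(atoms$resno)
  if (nrow(atoms) == 0L) abort("structure has no atoms")
  if (anyDuplicated(atoms$atom_id)) {
    abort(paste0("duplicated atom_id(s): ",
                 paste(unique(atoms$atom_id[duplicated(atoms$atom_id)]),
                       collapse = ", ")))
  }
  if (any(!nzchar(atoms$element))) abort("every atom needs a non-empty element")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    abort("non-finite coordinates in structure")
  }
  # a residue key (chain, resno) must map to exactly one residue name
  key <- paste(atoms$chain, atoms$resno, sep = ":")
  nm <- tapply(atoms$resname, key, function(v) length(unique(v)))
  if (any(nm > 1L)) {
    abort(paste0("residue key(s) with conflicting residue names: ",
                 paste(names(nm)[nm > 1L], collapse = ", ")))
  }
  attr(atoms, "title") <- title
  class(atoms) <- c("lox_structure", class(atoms))
  atoms
}

#' Load a structure from PDB or the plain-text fixture format
#'
#' PDB files are parsed with \pkg{bio3d}; both `ATOM` and `HETATM` records
#' become atoms and file order is preserved. The fixture-text format is a
#' tab-separated table with a header line
#' `atom_id name element chain resno resname x y z`.
#'
#' @param path File path.
#' @param format `"pdb"` or `"txt"`; guessed from the extension by default.
#' @return A `lox_structure` tibble.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "txt"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    elem <- a$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    # fall back on the leading alphabetic character of the atom name
    elem[blank] <- toupper(substr(gsub("[^A-Za-z].*$", "", a$elety[blank]), 1, 1))
    elem <- trimws(elem)
    elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))
    chain <- a$chain
    chain[is.na(chain) | !nzchar(chain)] <- "A"
    as_structure(tibble(
      atom_id = as.integer(a$eleno),
      name = trimws(a$elety),
      element = elem,
      chain = chain,
      resno = as.integer(a$resno),
      resname = trimws(a$resid),
      x = a$x, y = a$y, z = a$z
    ), title = basename(path))
  } else {
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, colClasses = NA),
      error = function(e) abort(paste0("cannot parse structure fixture '",
                                       path, "': ", conditionMessage(e)))
    )
    bad <- which(!stats::complete.cases(tab[, c("x", "y", "z")]))
    if (length(bad)) {
      abort(paste0("malformed coordinate record at data line ", bad[1],
                   " of ", path))
    }
    as_structure(tab, title = basename(path))
  }
}

#' Write a structure in the plain-text fixture format
#'
#' @param structure A `lox_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_text <- function(structure, path) {
  df <- as.data.frame(structure)
  df$x <- sprintf("%.6f", df$x)
  df$y <- sprintf("%.6f", df$y)
  df$z <- sprintf("%.6f", df$z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structure as PDB
#'
#' Gas ligands follow the HETATM dialect: residue `OXY` with atoms O1/O2,
#' residue `NO` with atoms N/O, iron as residue `FE` atom `FE`.
#'
#' @param structure A `lox_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  s <- structure
  xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("HETATM", nrow(s)),
    eleno = s$atom_id, elety = s$name, resid = s$resname,
    chain = s$chain, resno = s$resno, elesy = s$element
  )
  invisible(path)
}

#' Identify diatomic gas-ligand instances in a structure
#'
#' Each residue whose name appears in `naming_rules` becomes one ligand
#' instance labelled `"<resname>_<resno>"` (e.g. `OXY_701`, `NO_805`).
#'
#' @param structure A `lox_structure`.
#' @param naming_rules Named character vector mapping residue name to species,
#'   e.g. `c(OXY = "O2", NO = "NO")` (the default).
#' @return Tibble with columns `label`, `species`, `resno`, `chain`,
#'   and a list-column `atom_ids`.
#' @export
find_ligands <- function(structure, naming_rules = c(OXY = "O2", NO = "NO")) {
  expected_elements <- list(O2 = c("O", "O"), NO = c("N", "O"))
  hits <- structure[structure$resname %in% names(naming_rules), , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(label = character(), species = character(),
                  chain = character(), resno = integer(),
                  atom_ids = list()))
  }
  keys <- unique(paste(hits$chain, hits$resno, hits$resname, sep = "\r"))
  rows <- lapply(keys, function(k) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    sub <- hits[hits$chain == p[1] & hits$resno == as.integer(p[2]) &
                  hits$resname == p[3], , drop = FALSE]
    species <- unname(naming_rules[[p[3]]])
    exp_el <- expected_elements[[species]]
    if (!is.null(exp_el)) {
      if (nrow(sub) != length(exp_el)) {
        abort(paste0("residue ", p[3], " ", p[2], " has ", nrow(sub),
                     " atoms; species ", species, " expects ", length(exp_el)))
      }
      if (!identical(sort(sub$element), sort(exp_el))) {
        abort(paste0("residue ", p[3], " ", p[2],
                     " has elements inconsistent with species ", species))
      }
    }
    tibble(label = paste0(p[3], "_", p[2]), species = species,
           chain = p[1], resno = as.integer(p[2]),
           atom_ids = list(sub$atom_id))
  })
  out <- bind_rows(rows)
  arrange(out, .data$resno)
}

#' Residues within a radius of a centre atom
#'
#' A residue is included when at least one of its (by default heavy) atoms
#' lies within `radius` (inclusive) of the centre atom; minimum-image
#' distances are used when `box` is given.
#'
#' @param structure A `lox_structure`.
#' @param frame Optional n_atoms x 3 coordinate matrix; defaults to the
#'   structure's own coordinates.
#' @param center_atom_id Atom id of the centre (e.g. the catalytic iron).
#' @param radius Shell radius in Angstrom (default 20, the iron shell used
#'   for cross-run contact statistics).
#' @param include_hydrogens Include hydrogen atoms in the scan.
#' @param box Optional periodic box lengths.
#' @return Character vector of residue keys `"chain:resno:resname"`.
#' @export
residues_within <- function(structure, frame = NULL, center_atom_id,
                            radius = 20, include_hydrogens = FALSE,
                            box = NULL) {
  stopifnot_scalar_pos(radius, "radius")
  if (is.null(frame)) frame <- as.matrix(structure[, c("x", "y", "z")])
  crow <- atom_rows(structure, center_atom_id)
  rows <- seq_len(nrow(structure))
  if (!include_hydrogens) rows <- rows[structure$element[rows] != "H"]
  d2 <- cross_dist2(frame[rows, , drop = FALSE],
                    frame[crow, , drop = FALSE], box = box)[, 1]
  hit <- rows[d2 <= radius^2 + 1e-12]
  keys <- unique(res_key(structure$chain[hit], structure$resno[hit],
                         structure$resname[hit]))
  keys[order(res_key_number(keys))]
}

# Kabsch: optimal rotation (and translation) mapping B onto A in the
# least-squares sense. Returns list(R, tA, tB) with centroids.
kabsch <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, cA = cA, cB = cB)
}

#' Per-residue displacement between two conformations
#'
#' Superposes conformation B onto A by rigid least-squares (Kabsch) fit on
#' the `reference` residues, then reports the mean displacement of each
#' `region` residue's atoms. Used to compare two end-states of the same
#' protein, e.g. with and without a binding partner.
#'
#' @param struct_a,struct_b `lox_structure` tibbles with identical atom
#'   tables (coordinates may differ).
#' @param region Residue keys whose displacement is reported.
#' @param reference Residue keys used for the superposition (need at least
#'   three non-collinear atoms).
#' @param include_hydrogens Include hydrogens in both selections.
#' @return Tibble `residue`, `displacement` (mean Angstrom over the residue's
#'   atoms), with the reference-fit RMSD in attribute `reference_rmsd`.
#' @export
region_displacement <- function(struct_a, struct_b, region, reference,
                                include_hydrogens = FALSE) {
  if (nrow(struct_a) != nrow(struct_b) ||
      !identical(struct_a$atom_id, struct_b$atom_id)) {
    abort("the two structures must share the same atom table")
  }
  ref_rows <- residue_atom_rows(struct_a, reference, include_hydrogens)
  if (length(ref_rows) < 3L) abort("reference needs at least 3 atoms")
  A <- as.matrix(struct_a[, c("x", "y", "z")])
  B <- as.matrix(struct_b[, c("x", "y", "z")])
  refA <- A[ref_rows, , drop = FALSE]
  # collinearity check: rank of the centred reference coordinates
  sv <- svd(sweep(refA, 2, colMeans(refA)))$d
  if (sum(sv > 1e-8 * max(sv, 1)) < 2L) {
    abort("reference atoms are collinear; superposition is degenerate")
  }
  fit <- kabsch(A[ref_rows, , drop = FALSE], B[ref_rows, , drop = FALSE])
  Bfit <- sweep(sweep(B, 2, fit$cB) %*% t(fit$R), 2, fit$cA, "+")
  ref_rmsd <- sqrt(mean(rowSums((Bfit[ref_rows, , drop = FALSE] -
                                   A[ref_rows, , drop = FALSE])^2)))
  reg_rows <- residue_atom_rows(struct_a, region, include_hydrogens)
  if (!length(reg_rows)) abort("region residues resolve to no atoms")
  keys <- res_key(struct_a$chain[reg_rows], struct_a$resno[reg_rows],
                  struct_a$resname[reg_rows])
  disp <- sqrt(rowSums((Bfit[reg_rows, , drop = FALSE] -
                          A[reg_rows, , drop = FALSE])^2))
  out <- tibble(residue = keys, displacement = disp) %>%
    group_by(.data$residue) %>%
    summarise(displacement = mean(.data$displacement), .groups = "drop")
  out <- out[order(res_key_number(out$residue)), ]
  attr(out, "reference_rmsd") <- ref_rmsd
  out
}
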