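# Monoisotopic mass arithmetic for PE lipid species and their oxidized or
# nitrosylated derivatives, as used to assign negative-mode [M-H]- ions.

# IUPAC 2021 monoisotopic atomic masses (Da) of the elements needed here
MONOISOTOPIC_MASS <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, Fe = 55.9349421
)
PROTON_MASS <- 1.00727646688

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Named numeric vector of element counts, e.g.
#'   `c(C = 43, H = 78, N = 1, O = 8, P = 1)`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (!length(formula)) return(0)
  if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
    abort("formula must be a named vector of element counts")
  }
  unknown <- setdiff(names(formula), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(formula < 0)) abort("element counts must be non-negative")
  sum(formula * MONOISOTOPIC_MASS[names(formula)])
}

# combine two formulas (element-count addition)
add_formula <- function(a, b) {
  els <- union(names(a), names(b))
  out <- setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

#' Molecular formula of a diacyl-PE species
#'
#' Builds the formula constructively: glycerophosphoethanolamine backbone
#' (C5H14NO6P) plus two fatty acids CnH(2n-2d)O2 minus two waters for the
#' ester bonds, then the modification delta: hydroperoxy `+O2`, hydroxy
#' `+O`, nitroso `+NO -H` (radical-radical coupling of NO onto a
#' carbon-centered lipid radical).
#'
#' @param sn1,sn2 Length-2 vectors `c(carbons, double_bonds)` for the two
#'   acyl chains, e.g. `c(18, 0)` (stearoyl) and `c(20, 4)` (arachidonoyl).
#' @param modification `"none"`, `"hydroperoxy"`, `"hydroxy"` or
#'   `"nitroso"`.
#' @return Named count vector (a molecular formula).
#' @export
pe_species_formula <- function(sn1, sn2, modification = c("none",
                               "hydroperoxy", "hydroxy", "nitroso")) {
  modification <- match.arg(modification)
  acyl <- function(chain) {
    n <- chain[1]; d <- chain[2]
    if (n <= 0 || d < 0) abort("chain must have carbons > 0 and double bonds >= 0")
    if (d > (n - 2) / 2) {
      abort(paste0("infeasible unsaturation: ", n, " carbons cannot carry ",
                   d, " double bonds"))
    }
    c(C = n, H = 2 * n - 2 * d, O = 2)
  }
  backbone <- c(C = 5, H = 14, N = 1, O = 6, P = 1)
  f <- add_formula(backbone, acyl(sn1))
  f <- add_formula(f, acyl(sn2))
  f <- add_formula(f, c(H = -4, O = -2))  # two ester condensations
  delta <- switch(modification,
    none = c(C = 0),
    hydroperoxy = c(O = 2),
    hydroxy = c(O = 1),
    nitroso = c(N = 1, O = 1, H = -1)
  )
  f <- add_formula(f, delta)
  f[f != 0]
}

#' m/z of the deprotonated ion [M-H]-
#'
#' @param formula Molecular formula (must contain hydrogen).
#' @return Monoisotopic m/z of the singly deprotonated anion.
#' @export
mz_deprotonated <- function(formula) {
  if (is.null(formula["H"]) || is.na(formula["H"]) || formula["H"] < 1) {
    abort("cannot deprotonate a hydrogen-free formula")
  }
  unname(monoisotopic_mass(formula) - PROTON_MASS)
}

#' Parse a PE species string and report formula, mass and [M-H]-
#'
#' Accepts strings like `"PE(18:0/20:4)"`, `"PE(18:0/20:4)+NO"`,
#' `"PE(18:1/20:4)+OOH"`, `"PE(18:0/20:4)+OH"`.
#'
#' @param species Species string.
#' @return Tibble `species`, `formula` (Hill-ish string), `neutral_mass`,
#'   `mz_deprotonated`.
#' @export
pe_species_mz <- function(species) {
  m <- regmatches(species,
                  regexec("^PE\\((\\d+):(\\d+)/(\\d+):(\\d+)\\)(\\+NO|\\+OOH|\\+OH)?$",
                          species))[[1]]
  if (!length(m)) abort(paste0("cannot parse species string: ", species))
  modification <- switch(m[6], "+NO" = "nitroso", "+OOH" = "hydroperoxy",
                         "+OH" = "hydroxy", "none")
  f <- pe_species_formula(c(as.integer(m[2]), as.integer(m[3])),
                          c(as.integer(m[4]), as.integer(m[5])),
                          modification)
  ord <- c(intersect(c("C", "H", "N", "O", "P"), names(f)),
           setdiff(names(f), c("C", "H", "N", "O", "P")))
  fstr <- paste0(ord, ifelse(f[ord] == 1, "", f[ord]), collapse = "")
  tibble(species = species, formula = fstr,
         neutral_mass = monoisotopic_mass(f),
         mz_deprotonated = mz_deprotonated(f))
}
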