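#' Physical constants for tether mechanics
#'
#' Bundles the thermal energy and the polymer contour-length rises used
#' throughout the package. All downstream functions take a `constants`
#' object so temperature and contour conventions stay configurable in one
#' place.
#'
#' @param kBT Thermal energy in pN nm. Default 4.1 pN nm (room temperature).
#' @param aa_rise Contour length per amino acid residue of unfolded
#'   polypeptide, nm/residue. Default 0.365.
#' @param bp_rise Contour length per base pair of B-form double-stranded
#'   DNA, nm/bp. Default 0.338.
#' @param residues_per_AR Residues per ankyrin repeat. Default 33.
#' @param kcal_per_mol_pNnm Conversion: pN nm per kcal/mol. 1 kcal/mol =
#'   6.9477 pN nm (so kBT = 4.1 pN nm is about 0.59 kcal/mol).
#'
#' @return An object of class `constants`.
#' @examples
#' cst <- constants()
#' cst$kBT
#' @export
constants <- function(kBT = 4.1, aa_rise = 0.365, bp_rise = 0.338,
                      residues_per_AR = 33, kcal_per_mol_pNnm = 6.9477) {
  stopifnot(kBT > 0, aa_rise > 0, bp_rise > 0, residues_per_AR > 0,
            kcal_per_mol_pNnm > 0)
  structure(list(kBT = kBT, aa_rise = aa_rise, bp_rise = bp_rise,
                 residues_per_AR = residues_per_AR,
                 kcal_per_mol_pNnm = kcal_per_mol_pNnm),
            class = "constants")
}

#' @export
print.constants <- function(x, ...) {
  cat("constants: kBT =", x$kBT, "pN nm;",
      x$aa_rise, "nm/aa;", x$bp_rise, "nm/bp;",
      x$residues_per_AR, "aa/AR\n")
  invisible(x)
}

#' Contour length of an unfolded polypeptide
#'
#' @param n_residues Number of residues.
#' @param c A [constants()] object.
#' @return Contour length in nm (`n_residues * aa_rise`).
#' @export
residues_to_contour <- function(n_residues, c = constants()) {
  stopifnot(all(n_residues >= 0))
  n_residues * c$aa_rise
}

#' Contour length of double-stranded DNA
#'
#' @param n_bp Number of base pairs.
#' @param c A [constants()] object.
#' @return Contour length in nm (`n_bp * bp_rise`).
#' @export
bp_to_contour <- function(n_bp, c = constants()) {
  stopifnot(all(n_bp >= 0))
  n_bp * c$bp_rise
}
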