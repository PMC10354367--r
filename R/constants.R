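# Physical constants and per-element / per-residue lookup tables used across
# the feature modules. Values are package-versioned: changing any of them
# changes every downstream grid, so they live in one place.

#' Electrostatic conversion constant
#'
#' Coulomb's constant in kcal * Angstrom / (mol * e^2), the conventional
#' molecular-mechanics value, used to express pairwise electrostatic energies
#' in kcal/mol when charges are in elementary-charge units and distances in
#' Angstrom.
#'
#' @format A length-one numeric.
#' @export
COULOMB_CONSTANT <- 332.0636

# van der Waals radii (Angstrom), used as the Gaussian width when atom
# features are mapped onto the voxel grid and as Shrake-Rupley sphere radii.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, other = 1.80)

# single-bond covalent radii (Angstrom); bond detection uses
# r_i + r_j + 0.4 A as the distance criterion.
.COVALENT_RADII <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, other = 1.20)

# three-letter -> one-letter amino acid code map (20 canonical residues).
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.AA1 <- unname(.AA3TO1)
.AA1TO3 <- setNames(names(.AA3TO1), .AA3TO1)

# Maximum attainable solvent accessibilities (Angstrom^2) per residue, after
# Rost & Sander; relative accessibility = absolute SASA / this maximum.
.MAX_ASA <- c(
  A = 106, R = 248, N = 157, D = 163, C = 135,
  Q = 198, E = 194, G =  84, H = 184, I = 169,
  L = 164, K = 205, M = 188, F = 197, P = 136,
  S = 130, T = 142, W = 227, Y = 222, V = 142
)

#' Rost-Sander maximum accessibility table
#'
#' Returns the embedded table of per-residue maximum attainable solvent
#' accessibilities (A^2) used to normalize absolute SASA into relative
#' solvent accessibility (RSA).
#'
#' @return A named numeric vector over the 20 one-letter amino-acid codes.
#' @export
max_accessibility <- function() .MAX_ASA

#' Canonical amino-acid codes
#'
#' @return Character vector of the 20 one-letter codes, in the conventional
#'   alphabetical-by-three-letter order used throughout the package
#'   (channel order of the PSSM profile block).
#' @export
amino_acids <- function() .AA1

# element classification used by the density channels: C, N, O, S get their
# own channel; everything else (Se of MSE, metals, ...) maps to "other".
.classify_element <- function(el) {
  el <- toupper(trimws(el))
  ifelse(el %in% c("C", "N", "O", "S"), el, "other")
}

# derive an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, take the first letter (heavy atoms only).
.element_from_name <- function(name) {
  nm <- gsub("[0-9' ]", "", toupper(name))
  substr(nm, 1, 1)
}

.vdw_radius_of <- function(element) {
  unname(.VDW_RADII[ifelse(element %in% names(.VDW_RADII), element, "other")])
}

.covalent_radius_of <- function(element) {
  unname(.COVALENT_RADII[ifelse(element %in% names(.COVALENT_RADII), element, "other")])
}
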