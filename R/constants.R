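# Monoisotopic masses (Da). Residue masses are for amino-acid residues
# (i.e. the dehydrated form incorporated in a peptide chain).

#' Monoisotopic residue masses
#'
#' Named numeric vector of monoisotopic amino-acid residue masses in Da,
#' one entry per standard one-letter code.
#'
#' @format Named numeric vector of length 20.
#' @export
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Mass constants
#'
#' Monoisotopic mass constants (Da) used throughout the package: water,
#' the proton, the phospho modification (+79.96633), oxidation (+15.9949),
#' carbamidomethyl (+57.02146), the TMT reporter tag (+229.1629) and the
#' H3PO4 neutral loss (97.9769).
#'
#' @name mass-constants
#' @export
MASS_H2O <- 18.010565

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.007276

#' @rdname mass-constants
#' @export
MASS_PHOSPHO <- 79.96633

#' @rdname mass-constants
#' @export
MASS_OXIDATION <- 15.9949

#' @rdname mass-constants
#' @export
MASS_CARBAMIDOMETHYL <- 57.02146

#' @rdname mass-constants
#' @export
MASS_TMT <- 229.1629

#' @rdname mass-constants
#' @export
MASS_H3PO4 <- 97.9769

# Canonical modification-name -> mass table used by the PSM readers.
MOD_MASSES <- c(
  Phospho = 79.96633,
  Oxidation = 15.9949,
  Carbamidomethyl = 57.02146,
  TMT = 229.1629
)

# Residues that can carry a phospho group.
STY <- c("S", "T", "Y")
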