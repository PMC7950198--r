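# Physical constants and residue definitions.
#
# Monoisotopic element masses: IUPAC/CODATA. All residue and modification masses
# are derived from these elemental compositions so that mass and formula can
# never disagree.

.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.00727646688

# Average mass spacing between adjacent isotopologue peaks (~ one neutron).
.ISOTOPE_SPACING <- 1.0033548378

# Isotope abundances per element, indexed by neutron-number offset from the
# lightest isotope (IUPAC 2013 representative values). Offsets with zero
# abundance are included so positions line up during convolution.
.ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Amino-acid residue elemental compositions (residue = amino acid minus water).
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Glycan residue (dehydrated monosaccharide) compositions.
.GLYCAN_FORMULA <- list(
  HexNAc = c(C = 8, H = 13, N = 1, O = 5),  # N
  Hex    = c(C = 6, H = 10, N = 0, O = 5),  # H
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8), # S
  dHex   = c(C = 6, H = 10, N = 0, O = 4)   # F
)

.WATER_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
# Carbamidomethylation of cysteine (iodoacetamide), fixed modification.
.CAM_FORMULA <- c(C = 2, H = 3, N = 1, O = 1, S = 0)
# N-terminal Gln -> pyroglutamate: loss of ammonia.
.PYROGLU_FORMULA <- c(C = 0, H = -3, N = -1, O = 0, S = 0)

.AA_ALPHABET <- names(.RESIDUE_FORMULA)

#' @keywords internal
.formula_zero <- function() c(C = 0, H = 0, N = 0, O = 0, S = 0)

#' Add element-count vectors
#'
#' Named integer vectors over the CHNOS alphabet are used throughout as
#' elemental compositions; this sums any number of them.
#' @keywords internal
.formula_add <- function(...) {
  out <- .formula_zero()
  for (f in list(...)) {
    if (length(f) == 0) next
    out[names(f)] <- out[names(f)] + f
  }
  out
}

#' Monoisotopic mass of an element-count vector
#' @keywords internal
.formula_mass <- function(formula) {
  formula <- formula[formula != 0]
  if (length(formula) == 0) return(0)
  unknown <- setdiff(names(formula), names(.ELEMENT_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ELEMENT_MASS[names(formula)] * formula)
}

# Monoisotopic residue masses, derived once from the formulas.
.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, .formula_mass, numeric(1))
.GLYCAN_MASS <- vapply(.GLYCAN_FORMULA, .formula_mass, numeric(1))
.WATER_MASS <- .formula_mass(.WATER_FORMULA)
.CAM_MASS <- .formula_mass(.CAM_FORMULA)
.PYROGLU_MASS <- .formula_mass(.PYROGLU_FORMULA)
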