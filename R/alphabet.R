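#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in the fixed column order of PSI-BLAST
#' position-specific scoring matrices (ARNDCQEGHILKMFPSTWYV). All sparse
#' encodings, PSSM columns and propensity tables use this order.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# three-letter -> one-letter map for the 20 standard residues plus the
# common substitutions that are unambiguous parents (MSE selenomethionine,
# SEC selenocysteine, PYL pyrrolysine). Anything else is dropped by the
# structure reader with a warning.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K"
)

.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.aa_index <- function(aa) {
  idx <- match(aa, aa_alphabet())
  if (anyNA(idx)) {
    stop("unknown residue type(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  idx
}

.check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single non-missing seed is required")
  }
  as.integer(seed)
}
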