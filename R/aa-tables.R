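# Constant residue-level tables used across the package.

#' Canonical amino-acid alphabet
#'
#' The twenty canonical one-letter amino-acid codes, in alphabetical order.
#' This is also the fixed column order of the residue-count block of the
#' physicochemical feature vector.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy index
#'
#' Per-residue hydropathy values; positive is hydrophobic.
#'
#' @format Named numeric vector over the 20 canonical residues.
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Residue class sets for physicochemical features 21-24. Methionine belongs
# to both the amphipathic and polar sets; that double membership is
# intentional.
AA_CLASS_SETS <- list(
  hydrophobic = c("A", "I", "L", "F", "V"),
  amphipathic = c("W", "Y", "M"),
  polar       = c("Q", "N", "S", "T", "C", "M"),
  charged     = c("K", "R", "D", "E", "H")
)

# Bjellqvist/ExPASy-style pKa constants for the isoelectric-point solver.
# Positive groups gain a proton below their pKa; negative groups lose one
# above it. Termini are always counted once.
PKA_SET <- list(
  positive = c(Nterm = 7.50, K = 10.00, R = 12.00, H = 5.98),
  negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

# Standard BLOSUM62 half-bit substitution matrix (20 canonical residues).
BLOSUM62_MATRIX <- local({
  res <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(c(
     4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
    -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
    -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
    -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
     0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
    -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
    -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
     0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
    -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
    -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
    -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
    -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
    -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
    -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
    -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
     1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
     0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
    -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
    -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
     0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
  ), nrow = 20, byrow = TRUE, dimnames = list(res, res))
  m
})

#' BLOSUM62 substitution score
#'
#' Looks up the standard BLOSUM62 half-bit score for a residue pair. Scores
#' >= 0 are treated elsewhere in the package as evolutionarily conservative
#' substitutions.
#'
#' @param a,b Single canonical one-letter residue codes (vectorized,
#'   recycled to common length).
#' @return Integer score(s).
#' @examples
#' blosum62("D", "E")  # 2, a conservative substitution
#' blosum62("W", "G")  # -2
#' @export
blosum62 <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  bad <- !(a %in% AA_ALPHABET) | !(b %in% AA_ALPHABET)
  if (any(bad)) {
    stop("non-canonical residue in blosum62(): ",
         paste(unique(c(a[bad], b[bad])), collapse = ", "))
  }
  as.integer(BLOSUM62_MATRIX[cbind(a, b)])
}
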