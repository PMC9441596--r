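## Amino-acid constants and the composition matrix xi.
##
## All masses are average (not monoisotopic) and are derived from the
## polymeric (residue) molecular formulas, i.e. the free amino acid minus one
## water. Atomic masses are pinned below; residue masses are rounded to three
## decimals once, at table construction, and used identically everywhere so
## that the row-sum identity 1000 * sum_l xi_kl == proteinMW(seq_k) holds to
## the last bit.

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.WATER_MASS <- 18.015 # 2 H + O, g/mol

## residue formulas (polymerized, water-free), canonical 20-letter alphabet
.AA_FORMULA <- list(
  A = c(C = 3, H = 5,  N = 1, O = 1),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  D = c(C = 4, H = 5,  N = 1, O = 3),
  E = c(C = 5, H = 7,  N = 1, O = 3),
  F = c(C = 9, H = 9,  N = 1, O = 1),
  G = c(C = 2, H = 3,  N = 1, O = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  N = c(C = 4, H = 6,  N = 2, O = 2),
  P = c(C = 5, H = 7,  N = 1, O = 1),
  Q = c(C = 5, H = 8,  N = 2, O = 2),
  R = c(C = 6, H = 12, N = 4, O = 1),
  S = c(C = 3, H = 5,  N = 1, O = 2),
  T = c(C = 4, H = 7,  N = 1, O = 2),
  V = c(C = 5, H = 9,  N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9,  N = 1, O = 2)
)

.AA_NAME <- c(
  A = "alanine",       C = "cysteine",   D = "aspartate",  E = "glutamate",
  F = "phenylalanine", G = "glycine",    H = "histidine",  I = "isoleucine",
  K = "lysine",        L = "leucine",    M = "methionine", N = "asparagine",
  P = "proline",       Q = "glutamine",  R = "arginine",   S = "serine",
  T = "threonine",     V = "valine",     W = "tryptophan", Y = "tyrosine"
)

.residueMassTable <- function() {
  vapply(.AA_FORMULA, function(f) {
    round(sum(.ATOMIC_MASS[names(f)] * f), 3)
  }, numeric(1))
}

.AA_RESIDUE_MASS <- .residueMassTable()

#' Canonical amino-acid codes
#'
#' The twenty proteinogenic amino acids in the package's canonical order:
#' alphabetical by one-letter code. Every 20-vector and every column of a
#' composition matrix in this package follows this order.
#'
#' @return Character vector of the 20 one-letter codes.
#' @export
#' @examples
#' aminoAcidCodes()
aminoAcidCodes <- function() names(.AA_RESIDUE_MASS)

#' Amino-acid reference table
#'
#' @return A data.frame with one row per proteinogenic amino acid: one-letter
#'   \code{code}, full \code{name}, and average polymerized (water-free)
#'   \code{residue_mass} in g/mol.
#' @export
aminoAcidTable <- function() {
  data.frame(
    code = aminoAcidCodes(),
    name = unname(.AA_NAME[aminoAcidCodes()]),
    residue_mass = unname(.AA_RESIDUE_MASS),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Average residue mass of an amino acid
#'
#' Mass of the amino acid as polymerized in a peptide chain (free amino acid
#' minus one water), computed from the residue molecular formula with average
#' atomic masses.
#'
#' @param code One-letter amino-acid code(s); only the 20 canonical symbols
#'   are accepted. Ambiguity/extension codes (B, J, X, Z, U, O) are rejected.
#' @return Numeric vector of residue masses (g/mol), named by code.
#' @export
#' @examples
#' residueMass("G") # 57.052
#' residueMass(c("A", "W"))
residueMass <- function(code) {
  code <- toupper(as.character(code))
  bad <- !(code %in% aminoAcidCodes())
  if (any(bad)) {
    stop("non-canonical residue code(s): ",
         paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  .AA_RESIDUE_MASS[code]
}

#' Count residues of a protein sequence
#'
#' Tallies the occurrences of each of the 20 canonical amino acids in a
#' sequence, in canonical code order.
#'
#' @param sequence A character string over the one-letter alphabet.
#' @param strict If \code{TRUE} (default), any non-canonical character is an
#'   error naming its position; if \code{FALSE}, non-canonical characters are
#'   dropped with a warning (they then contribute no mass).
#' @return Integer vector of length 20, named by code, summing to the number
#'   of canonical residues in the sequence.
#' @export
#' @examples
#' countResidues("GGA")
countResidues <- function(sequence, strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  known <- chars %in% aminoAcidCodes()
  if (!all(known)) {
    pos <- which(!known)
    if (strict) {
      stop(sprintf("non-canonical residue '%s' at position %d",
                   chars[pos[1L]], pos[1L]), call. = FALSE)
    }
    warning(sprintf("dropping %d non-canonical residue(s) (first: '%s' at %d)",
                    length(pos), chars[pos[1L]], pos[1L]), call. = FALSE)
    chars <- chars[known]
  }
  counts <- table(factor(chars, levels = aminoAcidCodes()))
  out <- as.integer(counts)
  names(out) <- aminoAcidCodes()
  out
}

#' Molecular weight of a protein
#'
#' Residue-mass convention: the sum of the average residue masses of the
#' chain. This is the convention used throughout the pool accounting, because
#' it makes the amino-acid mass balances sum exactly to the enzyme mass drawn
#' from the protein pool. Set \code{terminalWater = TRUE} to obtain the mass
#' of the free polypeptide instead (one extra water, 18.015 g/mol); that
#' variant must not be used for composition-matrix or pool accounting.
#'
#' @param sequence Protein sequence string.
#' @param terminalWater Add one water for the free-chain mass (default
#'   \code{FALSE}).
#' @inheritParams countResidues
#' @return Molecular weight in g/mol; 0 for the empty sequence (without the
#'   terminal-water flag).
#' @export
#' @examples
#' proteinMW("GG")                       # 114.104
#' proteinMW("GG", terminalWater = TRUE) # 132.119
proteinMW <- function(sequence, terminalWater = FALSE, strict = TRUE) {
  counts <- countResidues(sequence, strict = strict)
  mw <- sum(counts * .AA_RESIDUE_MASS)
  if (terminalWater) mw <- mw + .WATER_MASS
  mw
}
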