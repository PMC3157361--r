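#' The twenty standard amino acids
#'
#' Single-letter codes of the standard amino-acid alphabet used throughout
#' the package.  All residue-pair matrices are indexed by this alphabet in
#' this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# 3-letter -> 1-letter, standard residues plus common 1:1 modified parents
aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # modified residues with an unambiguous standard parent
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", MLY = "K"
)

assert_aa_string <- function(seq, what = "sequence") {
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters, aa_alphabet())
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-standard letters: %s", what,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(letters)
}

#' Amino-acid composition of general protein surfaces
#'
#' Background frequencies used to draw random decoy ligand sequences.  The
#' bundled default fixes the glycine frequency at 6.9%, the value commonly
#' reported for glycine on protein surfaces and the boundary used for the
#' antibody-set glycine split; the remaining mass is distributed over the
#' other 19 residues following the broad surface trends (charged and polar
#' residues enriched, large hydrophobics depleted).
#'
#' @param freq Optional named numeric vector over [aa_alphabet()] to use
#'   instead of the bundled default.  It is renormalised to sum to 1.
#' @return Named numeric vector of length 20 summing to 1, with class
#'   `surface_composition`.
#' @export
#' @examples
#' comp <- surface_composition()
#' comp[["G"]]  # 0.069
surface_composition <- function(freq = NULL) {
  if (is.null(freq)) {
    freq <- c(
      A = 0.070, R = 0.058, N = 0.053, D = 0.066, C = 0.011,
      Q = 0.047, E = 0.078, G = 0.069, H = 0.024, I = 0.040,
      L = 0.068, K = 0.077, M = 0.017, F = 0.030, P = 0.052,
      S = 0.069, T = 0.056, W = 0.011, Y = 0.030, V = 0.049
    )
    # fill rounding slack on alanine so the vector sums to exactly 1
    freq[["A"]] <- freq[["A"]] + (1 - sum(freq))
  }
  if (!all(aa_alphabet() %in% names(freq))) {
    stop("composition must name all 20 standard amino acids", call. = FALSE)
  }
  freq <- freq[aa_alphabet()]
  if (any(freq < 0)) stop("composition frequencies must be non-negative", call. = FALSE)
  freq <- freq / sum(freq)
  structure(freq, class = c("surface_composition", "numeric"))
}

#' Uniform amino-acid composition
#'
#' @return Named numeric vector, each residue at 1/20.
#' @export
uniform_composition <- function() {
  surface_composition(stats::setNames(rep(1 / 20, 20), aa_alphabet()))
}

empty_pair_matrix <- function() {
  matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
}
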