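#' Synthetic general-purpose contact potential
#'
#' A 20x20 residue-pair contact table standing in for a generic (non
#' immune-specific) knowledge-based potential in comparison runs.  It is a
#' synthetic construction: the score of a pair is the product of the two
#' residues' Kyte-Doolittle hydropathies (scaled to \[-1, 1\]), so
#' hydrophobic-hydrophobic contacts score high and hydrophobic-polar
#' contacts score low -- the dominant signal in general contact-energy
#' tables.  It carries no immune-receptor-specific pair preferences, which
#' is exactly the property the evaluation campaigns contrast against.
#'
#' @return An object of class `interaction_potential` with
#'   `variant = "general_synthetic"`, maximum entry 1.0.
#' @seealso [derive_potential()] for the immune-specific potentials.
#' @export
#' @examples
#' gp <- synthetic_general_potential()
#' max(gp$matrix)  # 1
synthetic_general_potential <- function() {
  kd <- c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )[aa_alphabet()]
  h <- kd / max(abs(kd))
  m <- outer(h, h)
  m <- m / max(m)
  new_interaction_potential(m, variant = "general_synthetic",
                            max_before_norm = max(outer(h, h)),
                            meta = list(source = "synthetic hydropathy product"))
}
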