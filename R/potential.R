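#' @keywords internal
new_interaction_potential <- function(matrix, variant, max_before_norm, meta = list()) {
  stopifnot(identical(dim(matrix), c(20L, 20L)))
  dimnames(matrix) <- list(aa_alphabet(), aa_alphabet())
  structure(list(matrix = matrix, variant = variant,
                 max_before_norm = max_before_norm, meta = meta),
            class = "interaction_potential")
}

#' @export
print.interaction_potential <- function(x, ...) {
  cat(sprintf("<interaction_potential %s: 20x20, max %.3f, min %.3f>\n",
              x$variant, max(x$matrix), min(x$matrix)))
  invisible(x)
}

#' Build a sequence-randomised decoy of a complex
#'
#' Keeps the geometry and the receptor-side sequence of a complex and
#' resamples every ligand-side residue independently from a background
#' amino-acid composition (by default the general protein-surface
#' composition).  The decoy stands in for a non-binding receptor-ligand
#' pair in potential derivation and evaluation.
#'
#' @param cx A `complex_structure`.
#' @param comp A [surface_composition()].
#' @return A `complex_structure` with identical coordinates and receptor
#'   residues and randomised ligand residues.  Uses the current RNG
#'   stream; seed externally for reproducibility.
#' @export
make_decoy <- function(cx, comp = surface_composition()) {
  stopifnot(inherits(cx, "complex_structure"))
  comp <- surface_composition(comp)
  res <- cx$residues
  is_lig <- res$role == "ligand"
  res$aa[is_lig] <- sample(aa_alphabet(), sum(is_lig), replace = TRUE, prob = comp)
  out <- cx
  out$residues <- res
  out$id <- paste0(cx$id, "_decoy")
  out
}

#' Count interface amino-acid pairs across structures
#'
#' Tallies, over a set of complexes, how often each (receptor residue,
#' ligand residue) amino-acid pair occurs at the interface (C-alpha
#' distance <= cutoff).  Rows index the receptor residue, columns the
#' ligand residue.
#'
#' @param structures List of `complex_structure` objects.
#' @param cutoff Interface cutoff in Angstrom.
#' @param source Label recorded with the counts (`"crystal"` or
#'   `"random"`).
#' @return Object of class `pair_count_matrix`: list with `counts`
#'   (20x20), `n_structures`, `source`.
#' @export
count_pairs <- function(structures, cutoff = 8.0, source = "crystal") {
  if (length(structures) == 0) stop("need at least one structure", call. = FALSE)
  counts <- empty_pair_matrix()
  n_empty <- 0L
  for (cx in structures) {
    pairs <- extract_interface(cx, cutoff)
    if (nrow(pairs) == 0) {
      n_empty <- n_empty + 1L
      next
    }
    tab <- table(factor(pairs$receptor_aa, levels = aa_alphabet()),
                 factor(pairs$ligand_aa, levels = aa_alphabet()))
    counts <- counts + unclass(tab)
  }
  if (n_empty > 0) message(n_empty, " structure(s) had an empty interface and contributed nothing")
  structure(list(counts = counts, n_structures = length(structures), source = source),
            class = "pair_count_matrix")
}

#' Derive an immune-specific interaction potential
#'
#' Compares amino-acid pair counts at the interfaces of observed
#' ("crystal") complexes with the counts in sequence-randomised decoys and
#' subtracts the two, giving a 20x20 matrix in which positive entries mark
#' residue pairs enriched in real immune interfaces and negative entries
#' depleted ones.  Counts on each side are first divided by the number of
#' contributing structures (mean counts per structure) so that using more
#' than one decoy per crystal structure does not bias the difference.  The
#' matrix is finally normalised by its maximum entry, so the maximum is
#' exactly 1.0.
#'
#' @param crystal List of observed `complex_structure` objects.
#' @param variant One of `"IP_T"`, `"IP_B"`, `"IP_B_high"`, `"IP_B_low"`.
#' @param comp Background composition used for decoy ligand sequences.
#' @param decoys_per_structure Decoys generated per crystal structure.
#' @param cutoff Interface cutoff in Angstrom.
#' @param seed Optional seed for decoy generation; `NULL` uses the current
#'   RNG stream.
#' @return An `interaction_potential`.
#' @export
#' @examples
#' set.seed(1)
#' cxs <- fixture_campaign(40, "planted", seed = 2)
#' ip <- derive_potential(cxs, "IP_T", seed = 3)
#' which(ip$matrix == 1, arr.ind = TRUE)
derive_potential <- function(crystal,
                             variant = c("IP_T", "IP_B", "IP_B_high", "IP_B_low"),
                             comp = surface_composition(),
                             decoys_per_structure = 1,
                             cutoff = 8.0, seed = NULL) {
  variant <- match.arg(variant)
  if (length(crystal) == 0) stop("crystal set is empty", call. = FALSE)
  if (decoys_per_structure < 1) stop("decoys_per_structure must be >= 1", call. = FALSE)
  run <- function() {
    decoys <- unlist(lapply(crystal, function(cx) {
      lapply(seq_len(decoys_per_structure), function(i) make_decoy(cx, comp))
    }), recursive = FALSE)
    c_crystal <- count_pairs(crystal, cutoff, source = "crystal")
    c_random <- count_pairs(decoys, cutoff, source = "random")
    m_raw <- c_crystal$counts / c_crystal$n_structures -
      c_random$counts / c_random$n_structures
    mx <- max(m_raw)
    if (mx <= 0) stop("degenerate input: no residue pair is enriched over the decoys",
                      call. = FALSE)
    new_interaction_potential(
      m_raw / mx, variant, max_before_norm = mx,
      meta = list(n_structures = length(crystal),
                  decoys_per_structure = decoys_per_structure,
                  cutoff = cutoff,
                  composition = as.numeric(comp))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Glycine fraction of a ligand interface
#'
#' Fraction of distinct ligand-side interface residues that are glycine.
#' Antibody-antigen sets are split at 6.9% interface glycine -- the
#' frequency of glycine on general protein surfaces -- because antigens
#' with glycine-rich interfaces show a distinct recognition signature.
#'
#' @param cx A `complex_structure`.
#' @param cutoff Interface cutoff in Angstrom.
#' @return Fraction in \[0, 1\].  Errors on an empty interface.
#' @export
glycine_fraction <- function(cx, cutoff = 8.0) {
  pairs <- extract_interface(cx, cutoff)
  if (nrow(pairs) == 0) stop("empty interface: glycine fraction undefined", call. = FALSE)
  lig <- dplyr::distinct(pairs, .data$ligand_chain, .data$ligand_index, .data$ligand_aa)
  mean(lig$ligand_aa == "G")
}

#' Split antibody-antigen structures by interface glycine content
#'
#' @param structures List of `complex_structure` objects of kind
#'   `antibody_antigen`.
#' @param threshold Glycine-fraction boundary; strictly above goes to the
#'   high set, at or below to the low set (ties to low).
#' @param cutoff Interface cutoff in Angstrom.
#' @return List with elements `high` and `low`, an exhaustive disjoint
#'   partition of the input.
#' @export
split_by_glycine <- function(structures, threshold = 0.069, cutoff = 8.0) {
  if (length(structures) == 0) return(list(high = list(), low = list()))
  kinds <- vapply(structures, function(cx) cx$complex_kind, character(1))
  if (!all(kinds == "antibody_antigen")) {
    stop("glycine split applies to antibody_antigen complexes only", call. = FALSE)
  }
  fr <- vapply(structures, glycine_fraction, numeric(1), cutoff = cutoff)
  list(high = structures[fr > threshold], low = structures[fr <= threshold])
}

#' Score a complex with an interaction potential
#'
#' Mean potential value over the interface residue pairs of an observed
#' complex geometry (the structure-side analogue of [score_interaction()]).
#'
#' @param cx A `complex_structure`.
#' @param ip An `interaction_potential`.
#' @param cutoff Interface cutoff in Angstrom.
#' @return Mean potential value; errors on an empty interface.
#' @export
score_complex <- function(cx, ip, cutoff = 8.0) {
  stopifnot(inherits(ip, "interaction_potential"))
  pairs <- extract_interface(cx, cutoff)
  if (nrow(pairs) == 0) stop("empty interface: score undefined", call. = FALSE)
  mean(ip$matrix[cbind(pairs$receptor_aa, pairs$ligand_aa)])
}

#' Write / read a potential as labelled TSV
#'
#' The 20x20 matrix is serialised with explicit row (receptor) and column
#' (ligand) amino-acid headers to prevent transposition mistakes.
#'
#' @param ip An `interaction_potential`.
#' @param path Output file.
#' @return `write_potential` returns `path` invisibly; `read_potential`
#'   returns an `interaction_potential`.
#' @export
write_potential <- function(ip, path) {
  stopifnot(inherits(ip, "interaction_potential"))
  df <- data.frame(receptor_aa = rownames(ip$matrix), ip$matrix, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# interaction_potential variant=%s max_before_norm=%.10g",
                     ip$variant, ip$max_before_norm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  header <- readLines(path, n = 1)
  variant <- sub(".*variant=(\\S+).*", "\\1", header)
  mx <- as.numeric(sub(".*max_before_norm=(\\S+).*", "\\1", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  new_interaction_potential(m[aa_alphabet(), aa_alphabet()], variant, mx)
}
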