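#' Generate a random immune-receptor repertoire
#'
#' Receptor sequences (TCR or BCR) are independent uniform draws over the
#' 20-letter alphabet at a fixed, contact-template-matched length.
#'
#' @param n Number of receptors.
#' @param kind `"TCR"` or `"BCR"`.
#' @param length Sequence length; must equal the receptor dimension of the
#'   contact template used for scoring.
#' @param seed Integer seed.
#' @return Tibble: `receptor_id`, `kind`, `seq`.
#' @export
#' @examples
#' rep <- generate_repertoire(10, "TCR", length = 12, seed = 1)
generate_repertoire <- function(n, kind = c("TCR", "BCR"), length = 12, seed = 1) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(aa_alphabet(), length, replace = TRUE), collapse = "")
    }, character(1))
    tibble::tibble(receptor_id = sprintf("%s_%05d", kind, seq_len(n)),
                   kind = kind, seq = seqs)
  })
}

#' Compose the pMHC ligand sequence for a contact template
#'
#' TCR scoring treats the MHC groove plus the presented peptide as one
#' composite ligand surface.  The template's ligand dimension is filled
#' with the leading MHC residues followed by the peptide.
#'
#' @param mhc_seq MHC (pseudo-)sequence.
#' @param peptide Presented peptide.
#' @param cm The MHC's `contact_matrix`.
#' @return Ligand string of length `ncol(cm$m)`.
#' @export
pmhc_ligand_seq <- function(mhc_seq, peptide, cm) {
  n_lig <- ncol(cm$m)
  n_mhc <- n_lig - nchar(peptide)
  if (n_mhc < 0) stop("peptide longer than the template ligand dimension", call. = FALSE)
  if (nchar(mhc_seq) < n_mhc) stop("MHC sequence shorter than the template MHC part", call. = FALSE)
  paste0(substr(mhc_seq, 1, n_mhc), peptide)
}

#' Score many receptors against one ligand (vectorised)
#'
#' Batch form of [score_interaction()] for sequences of exactly the
#' template dimensions; used by thymic selection and the simulator where
#' thousands of receptor scores are needed per ligand.
#'
#' @param receptor_seqs Character vector of receptor sequences, each of
#'   length `nrow(cm$m)`.
#' @param ligand_seq Ligand sequence of length `ncol(cm$m)`.
#' @param cm A `contact_matrix`.
#' @param ip An `interaction_potential`.
#' @return Numeric vector of mean-over-contacts scores.
#' @export
score_receptors <- function(receptor_seqs, ligand_seq, cm, ip) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(ip, "interaction_potential"))
  lig <- assert_aa_string(ligand_seq, "ligand_seq")
  if (length(lig) != ncol(cm$m)) stop("ligand length must equal the template columns", call. = FALSE)
  if (any(nchar(receptor_seqs) != nrow(cm$m))) {
    stop("all receptor lengths must equal the template rows", call. = FALSE)
  }
  recmat <- do.call(rbind, strsplit(receptor_seqs, ""))
  contacts <- which(cm$m == 1, arr.ind = TRUE)
  total <- numeric(length(receptor_seqs))
  for (k in seq_len(nrow(contacts))) {
    total <- total + ip$matrix[cbind(recmat[, contacts[k, 1]], lig[contacts[k, 2]])]
  }
  total / nrow(contacts)
}

#' Thymic selection of a T-cell repertoire
#'
#' Implicit thymus model: every TCR is probed against each MHC allele
#' presenting each self-peptide, and its reactivity is the
#' potential-based interaction score.  Positive selection requires at
#' least weak reactivity to self-pMHC (maximum score over alleles and self
#' peptides at least `positive_min`); negative selection removes clones
#' whose maximum self reactivity exceeds `negative_max`.  Survivors keep
#' their input order; an empty survivor set is legal and reported.
#'
#' Numeric thresholds are calibration values, not measured biology; see
#' [calibrate_thresholds()] for a quantile-based choice that leaves a
#' target fraction of a random repertoire alive.
#'
#' @param repertoire Tibble from [generate_repertoire()] (kind TCR).
#' @param self_peptides Character vector of self peptides.
#' @param mhc_alleles Named character vector of MHC allele sequences.
#' @param ip_t The `IP_T` `interaction_potential`.
#' @param templates Contact-template library for [map_mhc_to_template()].
#' @param positive_min,negative_max Selection thresholds.
#' @return The surviving subset of `repertoire`, with a `self_reactivity`
#'   column (maximum score over alleles and self peptides).
#' @export
thymus_select <- function(repertoire, self_peptides, mhc_alleles, ip_t, templates,
                          positive_min = -1, negative_max = 0.5) {
  stopifnot(nrow(repertoire) > 0, length(self_peptides) > 0, length(mhc_alleles) > 0)
  if (positive_min > negative_max) {
    warning("positive_min exceeds negative_max; the survivor set will be empty",
            call. = FALSE)
  }
  max_score <- rep(-Inf, nrow(repertoire))
  for (a in seq_along(mhc_alleles)) {
    cm <- map_mhc_to_template(mhc_alleles[[a]], templates)
    for (pep in self_peptides) {
      s <- score_receptors(repertoire$seq, pmhc_ligand_seq(mhc_alleles[[a]], pep, cm),
                           cm, ip_t)
      max_score <- pmax(max_score, s)
    }
  }
  keep <- max_score >= positive_min & max_score <= negative_max
  if (!any(keep)) message("thymus selection removed the entire repertoire")
  out <- repertoire[keep, , drop = FALSE]
  out$self_reactivity <- max_score[keep]
  out
}

#' Choose thymic-selection thresholds from a reference repertoire
#'
#' Scores a random reference repertoire against the self background and
#' sets the negative threshold at the quantile that leaves
#' `target_survival` of clones alive (positive threshold at the complementary
#' lower quantile of a small floor fraction).
#'
#' @inheritParams thymus_select
#' @param n_reference Size of the reference repertoire.
#' @param target_survival Target surviving fraction.
#' @param floor_fraction Fraction removed at the bottom by positive
#'   selection.
#' @param length Receptor length.
#' @param seed Seed for the reference repertoire.
#' @return List with `positive_min` and `negative_max`.
#' @export
calibrate_thresholds <- function(self_peptides, mhc_alleles, ip_t, templates,
                                 n_reference = 500, target_survival = 0.5,
                                 floor_fraction = 0.05, length = 12, seed = 99) {
  ref <- generate_repertoire(n_reference, "TCR", length = length, seed = seed)
  max_score <- rep(-Inf, nrow(ref))
  for (a in seq_along(mhc_alleles)) {
    cm <- map_mhc_to_template(mhc_alleles[[a]], templates)
    for (pep in self_peptides) {
      s <- score_receptors(ref$seq, pmhc_ligand_seq(mhc_alleles[[a]], pep, cm), cm, ip_t)
      max_score <- pmax(max_score, s)
    }
  }
  list(
    positive_min = stats::quantile(max_score, floor_fraction, names = FALSE),
    negative_max = stats::quantile(max_score, floor_fraction + target_survival,
                                   names = FALSE)
  )
}

#' Write a repertoire to FASTA
#'
#' @param repertoire Tibble with `receptor_id` and `seq`.
#' @param path Output FASTA path.
#' @export
write_repertoire_fasta <- function(repertoire, path) {
  set <- Biostrings::AAStringSet(stats::setNames(repertoire$seq, repertoire$receptor_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read sequences from FASTA into a tibble
#'
#' @param path FASTA path.
#' @return Tibble: `receptor_id` (FASTA name), `seq`.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(receptor_id = names(set), seq = unname(as.character(set)))
}
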