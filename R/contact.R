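#' Build a binary contact matrix from a template structure
#'
#' Converts one complex geometry into a template of ones and zeros: entry
#' (i, j) is 1 exactly when receptor position i and ligand position j form
#' an interface pair (C-alpha distance <= cutoff).  The template is later
#' reused to score arbitrary receptor/ligand sequence pairs without any
#' structure of their own.
#'
#' @param template A `complex_structure` with a non-empty interface.
#' @param cutoff Interface cutoff in Angstrom.
#' @return Object of class `contact_matrix`: list with `template_id` and
#'   binary matrix `m` (rows = receptor positions, cols = ligand
#'   positions).
#' @export
build_contact_matrix <- function(template, cutoff = 8.0) {
  stopifnot(inherits(template, "complex_structure"))
  rec <- template$residues[template$residues$role == "receptor", ]
  lig <- template$residues[template$residues$role == "ligand", ]
  pairs <- extract_interface(template, cutoff)
  if (nrow(pairs) == 0) stop("template has an empty interface", call. = FALSE)
  m <- matrix(0L, nrow(rec), nrow(lig))
  ri <- match(paste(pairs$receptor_chain, pairs$receptor_index),
              paste(rec$chain_id, rec$seq_index))
  li <- match(paste(pairs$ligand_chain, pairs$ligand_index),
              paste(lig$chain_id, lig$seq_index))
  m[cbind(ri, li)] <- 1L
  structure(list(template_id = template$id, m = m), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix '%s': %d x %d, %d contacts>\n",
              x$template_id, nrow(x$m), ncol(x$m), sum(x$m)))
  invisible(x)
}

window_starts <- function(seq_len_total, dim_needed) {
  if (seq_len_total < dim_needed) {
    stop("sequence shorter than the contact-matrix dimension", call. = FALSE)
  }
  seq_len(seq_len_total - dim_needed + 1)
}

#' Score a receptor/ligand sequence pair on a contact template
#'
#' The interaction score is the mean potential value over the template's
#' contacts: sum of `ip$matrix[receptor[i], ligand[j]]` over all (i, j)
#' with a contact, divided by the number of contacts.  Because every
#' derived potential is normalised to a maximum of 1.0 the score never
#' exceeds 1.  Sequences longer than the template dimension are scored
#' over every contiguous window and the best (maximal) window score is
#' returned.
#'
#' @param receptor_seq,ligand_seq Amino-acid strings, length at least the
#'   corresponding contact-matrix dimension.
#' @param cm A `contact_matrix`.
#' @param ip An `interaction_potential`.
#' @return Numeric scalar score (<= 1).
#' @export
#' @examples
#' cx <- make_fixture_complex(2, 2, "AG", "GL", contact_fraction = 1, seed = 1)
#' cm <- build_contact_matrix(cx)
#' ip <- synthetic_general_potential()
#' score_interaction("AG", "GL", cm, ip)
score_interaction <- function(receptor_seq, ligand_seq, cm, ip) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(ip, "interaction_potential"))
  rec <- assert_aa_string(receptor_seq, "receptor_seq")
  lig <- assert_aa_string(ligand_seq, "ligand_seq")
  contacts <- which(cm$m == 1, arr.ind = TRUE)
  n_contact <- nrow(contacts)
  best <- -Inf
  for (rs in window_starts(length(rec), nrow(cm$m))) {
    for (ls in window_starts(length(lig), ncol(cm$m))) {
      s <- sum(ip$matrix[cbind(rec[contacts[, 1] + rs - 1],
                               lig[contacts[, 2] + ls - 1])]) / n_contact
      if (s > best) best <- s
    }
  }
  best
}

#' Map an interaction score to a probability
#'
#' The default map clamps the score to \[0, 1\]: derived potentials are
#' normalised to a maximum of 1.0 and the mean over contacts is bounded by
#' that maximum, so clamping is the minimal monotone map onto a
#' probability.  A logistic alternative is available for sensitivity
#' experiments.
#'
#' @param score Numeric score(s).
#' @param method `"clamp"` (default) or `"logistic"`.
#' @param slope,midpoint Logistic parameters (ignored for clamp).
#' @return Probability in \[0, 1\], monotone non-decreasing in `score`.
#' @export
score_to_probability <- function(score, method = c("clamp", "logistic"),
                                 slope = 5, midpoint = 0.25) {
  method <- match.arg(method)
  switch(method,
    clamp = pmin(pmax(score, 0), 1),
    logistic = stats::plogis(slope * (score - midpoint))
  )
}

#' Pick the contact template closest to an MHC sequence
#'
#' MHC alleles without a crystallised complex are mapped to the template
#' whose MHC sequence has the highest global-alignment identity; ties are
#' broken by lexical template id.
#'
#' @param mhc_seq Query MHC amino-acid sequence.
#' @param templates List of entries, each a list with `template_id`,
#'   `mhc_seq` and `cm` (a `contact_matrix`).
#' @return The chosen entry's `contact_matrix` (with the matched
#'   `template_id` attached).
#' @export
map_mhc_to_template <- function(mhc_seq, templates) {
  if (length(templates) == 0) stop("template library is empty", call. = FALSE)
  ids <- vapply(templates, function(t) t$template_id, character(1))
  idents <- vapply(templates, function(t) {
    sequence_identity(mhc_seq, t$mhc_seq)
  }, numeric(1))
  ord <- order(-idents, ids)
  templates[[ord[1]]]$cm
}

#' Global-alignment sequence identity
#'
#' Fraction of identical aligned positions under a Needleman-Wunsch global
#' alignment with match 1, mismatch 0 and unit gap cost.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  aas <- aa_alphabet()
  sm <- matrix(0, 20, 20, dimnames = list(aas, aas))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  Biostrings::pid(al, type = "PID1") / 100
}

#' Write / read a contact matrix as labelled TSV
#'
#' @param cm A `contact_matrix`.
#' @param path File path.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  df <- data.frame(receptor_pos = seq_len(nrow(cm$m)), cm$m, check.names = FALSE)
  colnames(df)[-1] <- paste0("L", seq_len(ncol(cm$m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_matrix template_id=%s", cm$template_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1)
  id <- sub(".*template_id=(\\S+).*", "\\1", header)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1, check.names = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- NULL
  structure(list(template_id = id, m = m), class = "contact_matrix")
}
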