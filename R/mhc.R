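#' Construct a position-specific scoring matrix
#'
#' A PSSM holds per-position amino-acid scores for one MHC allele and one
#' peptide length; a peptide's binding score is the sum over positions of
#' the matching entries.  `binder_threshold` marks the score above which a
#' peptide is considered a binder and anchors the presentation-probability
#' logistic.
#'
#' @param allele_id Allele label.
#' @param scores Numeric matrix, `peptide_length` rows x 20 columns named
#'   by [aa_alphabet()].
#' @param binder_threshold Numeric threshold on the summed score.
#' @param mhc_class `"I"` or `"II"`.
#' @return Object of class `pssm`.
#' @export
new_pssm <- function(allele_id, scores, binder_threshold = 0, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) stop("PSSM needs 20 amino-acid columns", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- aa_alphabet()
  scores <- scores[, aa_alphabet(), drop = FALSE]
  if (!all(is.finite(scores))) stop("PSSM entries must be finite", call. = FALSE)
  structure(list(allele_id = allele_id, peptide_length = nrow(scores),
                 scores = scores, binder_threshold = binder_threshold,
                 mhc_class = mhc_class),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm %s (MHC %s): %d-mer, binder threshold %.3f>\n",
              x$allele_id, x$mhc_class, x$peptide_length, x$binder_threshold))
  invisible(x)
}

#' Generate a synthetic PSSM fixture
#'
#' Draws independent standard-normal position/amino-acid scores and sets
#' the binder threshold at the given quantile of the score distribution of
#' random uniform peptides (estimated by simulation at build time), so a
#' controllable fraction of random peptides counts as binders.
#'
#' @param allele_id Allele label.
#' @param peptide_length Peptide length (class II uses a fixed 9-mer core).
#' @param mhc_class `"I"` or `"II"`.
#' @param seed Integer seed.
#' @param binder_quantile Quantile of random-peptide scores used as the
#'   binder threshold.
#' @return A `pssm`.
#' @export
make_fixture_pssm <- function(allele_id = "HLA_FIX", peptide_length = 9,
                              mhc_class = "I", seed = 1, binder_quantile = 0.95) {
  withr::with_seed(seed, {
    scores <- matrix(stats::rnorm(peptide_length * 20), peptide_length, 20,
                     dimnames = list(NULL, aa_alphabet()))
    random_scores <- replicate(2000, {
      pep <- sample.int(20, peptide_length, replace = TRUE)
      sum(scores[cbind(seq_len(peptide_length), pep)])
    })
    new_pssm(allele_id, scores,
             binder_threshold = stats::quantile(random_scores, binder_quantile,
                                                names = FALSE),
             mhc_class = mhc_class)
  })
}

#' Score a peptide against a PSSM
#'
#' @param p A `pssm`.
#' @param pep Peptide string of exactly the PSSM's length.
#' @return Numeric score: sum over positions of the per-position entry.
#' @export
score_peptide <- function(p, pep) {
  stopifnot(inherits(p, "pssm"))
  letters <- assert_aa_string(pep, "peptide")
  if (length(letters) != p$peptide_length) {
    stop(sprintf("peptide length %d does not match PSSM length %d",
                 length(letters), p$peptide_length), call. = FALSE)
  }
  sum(p$scores[cbind(seq_len(p$peptide_length), match(letters, colnames(p$scores)))])
}

#' Predict MHC-binding peptides within a protein
#'
#' Scores every length-l window of the protein with the PSSM and returns
#' the best `top_k`, ties broken by earlier start position.
#'
#' @param protein Protein sequence (length >= PSSM length).
#' @param p A `pssm`.
#' @param top_k Number of windows to return; capped at the number of
#'   windows with a message.
#' @param source_protein Label recorded with each peptide.
#' @return Tibble (class `peptide_set`): `peptide`, `start`, `score`,
#'   `source_protein`, `mhc_class`, `allele_id`.
#' @export
predict_binders <- function(protein, p, top_k = 1, source_protein = "protein") {
  stopifnot(inherits(p, "pssm"))
  letters <- assert_aa_string(protein, "protein")
  l <- p$peptide_length
  if (length(letters) < l) stop("protein shorter than the PSSM length", call. = FALSE)
  starts <- seq_len(length(letters) - l + 1)
  peps <- vapply(starts, function(s) paste(letters[s:(s + l - 1)], collapse = ""), character(1))
  scores <- vapply(peps, function(pep) score_peptide(p, pep), numeric(1), USE.NAMES = FALSE)
  if (top_k > length(starts)) {
    message("top_k exceeds the ", length(starts), " available windows; returning all")
    top_k <- length(starts)
  }
  ord <- order(-scores, starts)[seq_len(top_k)]
  out <- tibble::tibble(peptide = peps[ord], start = starts[ord], score = scores[ord],
                        source_protein = source_protein,
                        mhc_class = p$mhc_class, allele_id = p$allele_id)
  class(out) <- c("peptide_set", class(out))
  out
}

#' Keep the self-peptides most similar to an injected peptide
#'
#' Thymic-selection runtime scales with the self-peptide pool, and only
#' peptides resembling the injected one can interfere with it; the pool is
#' therefore reduced to the `k` members with the highest global-alignment
#' identity to the injected peptide (ties by pool order).
#'
#' @param pool Character vector of self-peptide sequences.
#' @param injected Injected peptide sequence.
#' @param k Number to retain (default 50); the whole pool is returned if
#'   it is not larger than `k`.
#' @return Character vector of `min(k, length(pool))` peptides.
#' @export
select_self_peptides <- function(pool, injected, k = 50) {
  if (length(pool) == 0) stop("self-peptide pool is empty", call. = FALSE)
  if (length(pool) <= k) return(pool)
  sim <- vapply(pool, function(s) sequence_identity(s, injected), numeric(1),
                USE.NAMES = FALSE)
  ord <- order(-sim, seq_along(pool))
  pool[sort(ord[seq_len(k)])]
}

#' Probability that a scored peptide is presented
#'
#' Monotone logistic map of the PSSM score relative to the binder
#' threshold: a peptide scoring exactly at threshold is presented with
#' probability 0.5, strong binders approach 1.
#'
#' @param score PSSM score(s).
#' @param p The `pssm` providing the threshold.
#' @param slope Logistic slope per score unit.
#' @return Probability in (0, 1).
#' @export
presentation_probability <- function(score, p, slope = 1) {
  stopifnot(inherits(p, "pssm"))
  stats::plogis(slope * (score - p$binder_threshold))
}

#' Write / read a PSSM as labelled TSV
#'
#' Tab-separated dialect: a comment header carrying allele metadata, then
#' a header row of amino acids and one row per peptide position.
#'
#' @param p A `pssm`.
#' @param path File path.
#' @export
write_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pssm allele_id=%s mhc_class=%s binder_threshold=%.10g",
                     p$allele_id, p$mhc_class, p$binder_threshold), con)
  df <- data.frame(pos = seq_len(p$peptide_length), p$scores, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  header <- readLines(path, n = 1)
  allele <- sub(".*allele_id=(\\S+).*", "\\1", header)
  cls <- sub(".*mhc_class=(\\S+).*", "\\1", header)
  thr <- as.numeric(sub(".*binder_threshold=(\\S+).*", "\\1", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1, check.names = FALSE)
  new_pssm(allele, as.matrix(df[, -1]), binder_threshold = thr, mhc_class = cls)
}
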