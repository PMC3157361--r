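#' Split structures into training and validation sets
#'
#' Deterministic (per seed) random partition.  The training size is
#' `round(frac_train * n)` with halves rounded away from zero, matching a
#' 90/10 split convention (n = 33 gives 30/3).
#'
#' @param structures List of structures (any list).
#' @param frac_train Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
split_train_validation <- function(structures, frac_train = 0.9, seed = 1) {
  n <- length(structures)
  if (n < 2) stop("need at least two structures to split", call. = FALSE)
  if (frac_train <= 0 || frac_train >= 1) stop("frac_train must be in (0, 1)", call. = FALSE)
  n_train <- floor(frac_train * n + 0.5)  # round half away from zero
  n_train <- min(max(n_train, 1), n - 1)
  withr::with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train = structures[idx], validation = structures[-idx])
  })
}

#' Mann-Whitney AUC and significance
#'
#' The area under the ROC curve equals U / (n1 * n2), the fraction of
#' (positive, negative) score pairs ordered correctly with ties counted as
#' one half.  The two-sided p-value uses the tie-corrected normal
#' approximation of the Mann-Whitney test; below 8 observations per group
#' (and without ties across groups at identical values being an issue) the
#' exact permutation null of U is enumerated instead.
#'
#' @param pos_scores,neg_scores Numeric score vectors (positives expected
#'   to score higher).
#' @return List with `auc` and `p_value`.
#' @export
#' @examples
#' mann_whitney_auc(c(2, 3), c(0, 1))  # complete separation, auc 1
mann_whitney_auc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  if (n1 == 0 || n2 == 0) stop("both score sets must be non-empty", call. = FALSE)
  all_scores <- c(pos_scores, neg_scores)
  r <- rank(all_scores)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  if (length(unique(all_scores)) == 1) {
    return(list(auc = 0.5, p_value = 1.0))
  }
  if (min(n1, n2) < 8 && choose(n1 + n2, n1) <= 200000) {
    # exact permutation distribution of U
    combs <- utils::combn(n1 + n2, n1)
    u_null <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_null - mu) >= abs(u - mu) - 1e-12)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(all_scores)
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p_value = min(p, 1))
}

#' Run a full potential derivation and evaluation campaign
#'
#' Splits the observed set 90/10, derives the potential on the training
#' crystals only, generates fresh decoys for both subsets (validation
#' decoys are never reused from training), scores every structure, and
#' summarises separation of crystal from decoy scores with the
#' Mann-Whitney AUC in both subsets.
#'
#' @param crystal_set List of `complex_structure` objects.
#' @param variant Potential variant tag (see [derive_potential()]).
#' @param comp Decoy composition.
#' @param decoys_per_structure Decoys per structure for derivation and
#'   scoring.
#' @param frac_train Training fraction.
#' @param seed Campaign seed (split, decoys, derivation).
#' @param score_with Optional `interaction_potential` used for scoring
#'   instead of the freshly derived one (e.g. a general contact potential
#'   for head-to-head comparison); derivation still runs on the training
#'   set so the campaign structure is identical.
#' @param cutoff Interface cutoff in Angstrom.
#' @return Object of class `ip_evaluation`: list with `potential`, tibble
#'   `scores` (columns subset, label, score), tibble `summary` (per
#'   subset/label mean, sd, n), `auc` tibble (subset, auc, p_value) plus a
#'   pooled row.
#' @export
evaluate_potential <- function(crystal_set,
                               variant = "IP_T",
                               comp = surface_composition(),
                               decoys_per_structure = 1,
                               frac_train = 0.9,
                               seed = 1,
                               score_with = NULL,
                               cutoff = 8.0) {
  sets <- split_train_validation(crystal_set, frac_train, seed = seed)
  ip <- derive_potential(sets$train, variant, comp, decoys_per_structure,
                         cutoff = cutoff, seed = seed + 1)
  scorer <- if (is.null(score_with)) ip else score_with
  score_subset <- function(structures, subset, decoy_seed) {
    withr::with_seed(decoy_seed, {
      crystal_scores <- vapply(structures, score_complex, numeric(1),
                               ip = scorer, cutoff = cutoff)
      decoy_scores <- unlist(lapply(structures, function(cx) {
        vapply(seq_len(decoys_per_structure), function(i) {
          score_complex(make_decoy(cx, comp), scorer, cutoff)
        }, numeric(1))
      }))
      dplyr::bind_rows(
        tibble::tibble(subset = subset, label = "crystal", score = crystal_scores),
        tibble::tibble(subset = subset, label = "random", score = decoy_scores)
      )
    })
  }
  scores <- dplyr::bind_rows(
    score_subset(sets$train, "train", seed + 2),
    score_subset(sets$validation, "validation", seed + 3)
  )
  summary <- scores |>
    dplyr::group_by(.data$subset, .data$label) |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     n = dplyr::n(), .groups = "drop")
  auc_row <- function(sub) {
    s <- if (sub == "pooled") scores else scores[scores$subset == sub, ]
    res <- mann_whitney_auc(s$score[s$label == "crystal"], s$score[s$label == "random"])
    tibble::tibble(subset = sub, auc = res$auc, p_value = res$p_value)
  }
  auc <- dplyr::bind_rows(auc_row("train"), auc_row("validation"), auc_row("pooled"))
  structure(list(potential = ip, scored_with = scorer$variant,
                 scores = scores, summary = summary, auc = auc,
                 n_structures = length(crystal_set)),
            class = "ip_evaluation")
}

#' @export
print.ip_evaluation <- function(x, ...) {
  cat(sprintf("<ip_evaluation: %s derived on %d structures, scored with %s>\n",
              x$potential$variant, x$n_structures, x$scored_with))
  print(x$auc)
  invisible(x)
}

#' Tidy an evaluation campaign
#'
#' @param x An `ip_evaluation`.
#' @param ... Unused.
#' @return Tibble of per-subset, per-label score summaries (mean, sd, n),
#'   as drawn in grouped bar charts of crystal vs random scores.
#' @method tidy ip_evaluation
#' @export
tidy.ip_evaluation <- function(x, ...) x$summary

#' One-row summary of an evaluation campaign
#'
#' @param x An `ip_evaluation`.
#' @param ... Unused.
#' @return One-row tibble: variant, training and validation AUC with
#'   p-values, structure count.
#' @method glance ip_evaluation
#' @export
glance.ip_evaluation <- function(x, ...) {
  a <- x$auc
  tibble::tibble(
    variant = x$potential$variant,
    scored_with = x$scored_with,
    auc_train = a$auc[a$subset == "train"],
    p_train = a$p_value[a$subset == "train"],
    auc_validation = a$auc[a$subset == "validation"],
    p_validation = a$p_value[a$subset == "validation"],
    auc_pooled = a$auc[a$subset == "pooled"],
    n_structures = x$n_structures
  )
}

#' Bar chart of crystal vs random score separation
#'
#' @param object An `ip_evaluation`.
#' @param ... Unused.
#' @return A ggplot: mean +/- sd score per subset and label.
#' @method autoplot ip_evaluation
#' @export
autoplot.ip_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$subset, y = .data$mean, fill = .data$label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean interface score",
                  fill = NULL,
                  title = sprintf("%s: crystal vs random separation",
                                  object$potential$variant)) +
    ggplot2::theme_minimal()
}
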