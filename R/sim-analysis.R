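#' Classify a treatment outcome
#'
#' A treatment is a success when the final cancer count is strictly below
#' the count at the beginning of treatment.
#'
#' @param x An `immune_sim`, or a series tibble with a `cancer` column.
#' @param initial_cancer Needed only when `x` is a bare series.
#' @return `"success"` or `"failure"`.
#' @export
classify_outcome <- function(x, initial_cancer = NULL) {
  if (inherits(x, "immune_sim")) {
    final <- x$final_cancer
    initial_cancer <- x$config$initial_cancer
  } else {
    final <- x$cancer[nrow(x)]
    if (is.null(initial_cancer)) stop("initial_cancer required for a bare series",
                                      call. = FALSE)
  }
  if (final < initial_cancer) "success" else "failure"
}

#' Reactiveness of a treatment against unlimited growth
#'
#' Percent reduction of the final tumor burden relative to the untreated
#' trajectory: `100 * (1 - final_treated / final_untreated)`, floored at
#' zero; 100% means complete eradication.
#'
#' @param treated,untreated `immune_sim` objects (equal duration).
#' @return Percentage in \[0, 100\].
#' @export
reactiveness <- function(treated, untreated) {
  stopifnot(inherits(treated, "immune_sim"), inherits(untreated, "immune_sim"))
  if (treated$config$duration != untreated$config$duration) {
    stop("runs must have equal duration", call. = FALSE)
  }
  fu <- untreated$final_cancer
  if (fu == 0) stop("untreated final count is zero; reactiveness undefined", call. = FALSE)
  max(0, 100 * (1 - treated$final_cancer / fu))
}

first_reduction_step <- function(sim) {
  s <- sim$series
  hit <- which(s$cancer < sim$config$initial_cancer & s$step > 0)
  if (length(hit) == 0) NA_integer_ else s$step[hit[1]]
}

#' Activation-state propensities among failing runs
#'
#' For a set of replicate runs of one experiment, records which key
#' populations (active cytotoxic and helper T-cells, presenting dendritic
#' cells and macrophages) ever appeared in each run, computes the
#' fraction of *failing* runs in which each population was present, and
#' labels the experiment `frequent_failures` (success rate below 50%) or
#' `rare_failures`.
#'
#' @param runs List of `immune_sim` objects.
#' @return List with `propensity` (tibble population/fraction over failing
#'   runs), `success_rate`, and `group`.
#' @export
failure_profile <- function(runs) {
  stopifnot(length(runs) > 0)
  pops <- c("TC_active", "TH_active", "DC_presenting_I",
            "DC_presenting_II", "MA_presenting_II")
  present <- t(vapply(runs, function(r) {
    vapply(pops, function(p) any(r$series[[p]] > 0), logical(1))
  }, logical(length(pops))))
  outcomes <- vapply(runs, classify_outcome, character(1))
  success_rate <- mean(outcomes == "success")
  failing <- outcomes == "failure"
  propensity <- if (any(failing)) {
    tibble::tibble(population = pops,
                   propensity = unname(colMeans(present[failing, , drop = FALSE])))
  } else {
    tibble::tibble(population = character(0), propensity = numeric(0))
  }
  list(propensity = propensity, success_rate = success_rate,
       group = if (success_rate < 0.5) "frequent_failures" else "rare_failures")
}

#' Sweep a multiplicative bias on the recognition probabilities
#'
#' Re-runs the simulation with every potential-derived interaction
#' probability multiplied by each factor (then clamped to \[0, 1\]),
#' summarising per factor the mean final tumor size relative to the
#' initial size, the mean number of steps until the tumor first drops
#' below its initial size, and the fraction of successful runs.
#'
#' @param cfg Base `sim_config`.
#' @param factors Positive multipliers (1 reproduces the unbiased runs).
#' @param replicates Replicate runs per factor, each with its own seed
#'   derived from `cfg$seed`.
#' @return Tibble: `factor`, `mean_relative_final_tumor`,
#'   `mean_steps_to_reduction` (NA when no run reduced the tumor),
#'   `success_fraction`, `n_runs`.
#' @export
bias_sweep <- function(cfg, factors = c(0.5, 0.75, 1, 1.25, 1.5), replicates = 10) {
  stopifnot(all(factors >= 0), replicates >= 1)
  rows <- lapply(seq_along(factors), function(i) {
    runs <- lapply(seq_len(replicates), function(r) {
      cfg_i <- cfg
      cfg_i$bias <- factors[i]
      cfg_i$seed <- cfg$seed + (i - 1L) * replicates + r
      run_simulation(cfg_i)
    })
    finals <- vapply(runs, function(x) x$final_cancer, numeric(1))
    steps <- vapply(runs, first_reduction_step, integer(1))
    tibble::tibble(
      factor = factors[i],
      mean_relative_final_tumor = mean(finals) / cfg$initial_cancer,
      mean_steps_to_reduction = if (all(is.na(steps))) NA_real_
                                else mean(steps, na.rm = TRUE),
      success_fraction = mean(vapply(runs, classify_outcome, character(1)) == "success"),
      n_runs = replicates
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a bias sweep
#'
#' @param object Tibble returned by [bias_sweep()].
#' @return ggplot of relative final tumor and success fraction vs factor.
#' @export
plot_bias_sweep <- function(object) {
  df <- tidyr::pivot_longer(object,
                            c("mean_relative_final_tumor", "success_fraction"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$value)) +
    ggplot2::geom_col(fill = "firebrick", width = 0.08) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "bias multiplier on interaction probability", y = NULL) +
    ggplot2::theme_minimal()
}
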