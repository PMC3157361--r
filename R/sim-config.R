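#' Steps per simulated day and year
#'
#' One lattice time step corresponds to 8 hours, so a day is 3 steps and
#' one simulated year is 365 * 3 = 1095 steps.
#'
#' @return Integer number of steps.
#' @export
steps_per_day <- function() 3L

#' @rdname steps_per_day
#' @export
steps_per_year <- function() 365L * steps_per_day()

#' Build a vaccination schedule
#'
#' Injection time points for a prime plus `n_boosts` boosts at a fixed
#' day interval, expressed in 8-hour lattice steps.
#'
#' @param start_step First injection step.
#' @param n_boosts Number of repeat injections after the first.
#' @param interval_days Days between injections.
#' @return Integer vector of injection steps.
#' @export
#' @examples
#' build_schedule()  # 0, 84, 168, 252, 336, 420
build_schedule <- function(start_step = 0, n_boosts = 5, interval_days = 28) {
  if (interval_days <= 0) stop("interval_days must be positive", call. = FALSE)
  start_step + (0:n_boosts) * (interval_days * steps_per_day())
}

#' Default per-step rates of the lattice simulation
#'
#' Every kinetic constant the step rules use lives here, documented and
#' overridable.  Values are desk-scale calibrations chosen for a ~20^3
#' lattice holding hundreds of agents:
#'
#' * `sites_per_ul` (1600): lattice sites per microlitre; 5 ul gives a
#'   20^3 grid.
#' * `density_per_ul`: resting leukocytes seeded per microlitre by type
#'   (scaled far below physiologic counts to keep agent numbers tractable).
#' * `p_phagocytosis` (0.9): chance an APC at an antigen-bearing site
#'   ingests antigen in one step; macrophages additionally require local
#'   danger signal.
#' * `p_duplicate` (0.3): per-step division probability of an activated
#'   lymphocyte; multiplied by `1 + il2_boost` when IL-2 is present.
#' * `division_budget` (6): divisions available per activation event
#'   (clonal burst size <= 2^budget), renewed on memory re-activation.
#' * `p_active_death` (0.05): per-step death probability of an activated
#'   effector T-cell (contraction of the response).
#' * `p_memory` (0.1): fraction of divisions producing a memory cell.
#' * `memory_bonus` (2): multiplicative recognition bonus of memory cells.
#' * `p_kill_apc` (0.5): chance an activated cytotoxic T-cell kills a
#'   co-located presenting APC in one step.
#' * `p_b_stimulation` (0.5): chance a presenting B-cell co-located with
#'   an active helper T-cell differentiates (plasma + memory).
#' * `antibody_per_plasma` (5), `antigen_clear_per_antibody` (0.1):
#'   humoral stoichiometry per site and step.
#' * `p_stop_present` (0.02): per-step chance a presenting APC loses its
#'   peptide-MHC complexes and returns to surveillance (mean presentation
#'   episode ~50 steps, about 17 days).
#' * `p_plasma_death` (0.02): per-step death probability of a plasma
#'   cell (mean secretory lifespan ~17 days).
#' * `il2_per_th` (1): IL-2 units secreted per active helper per step.
#' * `decay_*`: per-step molecule retention factors (values below
#'   `molecule_floor` are zeroed).
#' * `chemotaxis_p` (0.8): chance an activated T-cell steps toward the
#'   tumor centroid instead of walking randomly.
#' * `cancer_division_p`: per-cell, per-step division probability set so
#'   an untreated tumor doubles over one simulated year,
#'   `(1 + p)^1095 = 2`.
#' * `antigen_dose`, `danger_dose`: per-site amounts deposited by one
#'   injection (uniform distribution through the volume).
#' * `max_agents` (20000): hard cap on concurrently alive immune agents.
#'
#' @return Named list of rates.
#' @export
default_rates <- function() {
  list(
    sites_per_ul = 1600,
    density_per_ul = c(TH = 16, TC = 20, B = 12, MA = 8, DC = 8),
    p_phagocytosis = 0.9,
    p_duplicate = 0.3,
    division_budget = 6,
    p_active_death = 0.05,
    p_memory = 0.1,
    memory_bonus = 2,
    il2_boost = 0.5,
    p_kill_apc = 0.5,
    p_b_stimulation = 0.5,
    antibody_per_plasma = 5,
    antigen_clear_per_antibody = 0.1,
    p_stop_present = 0.02,
    p_plasma_death = 0.02,
    il2_per_th = 1,
    decay_antigen = 0.95,
    decay_antibody = 0.95,
    decay_il2 = 0.8,
    decay_danger = 0.9,
    molecule_floor = 1e-3,
    chemotaxis_p = 0.8,
    cancer_division_p = 2^(1 / 1095) - 1,
    antigen_dose = 2,
    danger_dose = 1,
    max_agents = 20000
  )
}

#' Assemble a simulation configuration
#'
#' Collects every input of the lattice model: geometry, tumor size,
#' schedule, MHC genotype, injected peptides, potentials, contact
#' templates, PSSMs, self peptides, thymic thresholds and kinetic rates.
#' [demo_config()] builds a complete synthetic instance.
#'
#' @param volume_ul Simulated blood volume in microlitres.
#' @param initial_cancer Initial cancer-cell count (placed contiguously as
#'   a solid tumor at the lattice centre).
#' @param duration Number of 8-hour steps.
#' @param schedule Injection steps (see [build_schedule()]); `integer(0)`
#'   disables treatment.
#' @param adjuvant Logical: co-inject the danger signal.
#' @param mhc_I,mhc_II Named character vectors of MHC allele sequences.
#' @param peptides_I,peptides_II Injected peptides per MHC class.
#' @param antigen_protein Tumor antigen sequence (its best class-I binder
#'   is the epitope cancer cells present).
#' @param self_peptides Self peptides used by thymic selection.
#' @param ip_t,ip_b_high,ip_b_low Interaction potentials.
#' @param templates_I,templates_II MHC contact-template libraries (entries
#'   with `template_id`, `mhc_seq`, `cm`).
#' @param template_b Antibody contact template (`contact_matrix`).
#' @param pssms_I,pssms_II Lists of `pssm`, one per allele (same order as
#'   `mhc_I` / `mhc_II`).
#' @param thymus List with `positive_min`, `negative_max`.
#' @param rates Kinetic rates, see [default_rates()].
#' @param prob_method,prob_slope,prob_midpoint Strategy mapping interaction
#'   scores to probabilities inside the simulation (see
#'   [score_to_probability()]).  The default logistic map spreads the
#'   near-zero mean-over-contacts scores of random receptors into a graded
#'   probability scale; `"clamp"` uses the raw clamped score.
#' @param bias Multiplier applied to every potential-derived recognition
#'   probability (the sensitivity dial of [bias_sweep()]).
#' @param recognition_override If non-`NULL`, replaces every recognition
#'   and presentation probability by this value (0 or 1 give the
#'   no-interaction and saturation controls).
#' @param seed Run seed.
#' @param stop_when_eradicated Stop stepping once the tumor is gone and
#'   carry terminal counts forward in the series.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(volume_ul = 5, initial_cancer = 100,
                       duration = steps_per_year(),
                       schedule = build_schedule(), adjuvant = TRUE,
                       mhc_I, mhc_II, peptides_I, peptides_II,
                       antigen_protein, self_peptides,
                       ip_t, ip_b_high, ip_b_low,
                       templates_I, templates_II, template_b,
                       pssms_I, pssms_II,
                       thymus = list(positive_min = -1, negative_max = 0.5),
                       rates = default_rates(),
                       prob_method = c("logistic", "clamp"),
                       prob_slope = 5, prob_midpoint = 0.25,
                       bias = 1, recognition_override = NULL,
                       seed = 1, stop_when_eradicated = TRUE) {
  stopifnot(volume_ul > 0, duration >= 0, initial_cancer >= 0)
  if (length(schedule) > 0 && any(schedule > duration)) {
    stop("schedule steps must lie within the duration", call. = FALSE)
  }
  cfg <- list(volume_ul = volume_ul, initial_cancer = initial_cancer,
              duration = as.integer(duration), schedule = as.integer(schedule),
              adjuvant = isTRUE(adjuvant),
              mhc_I = mhc_I, mhc_II = mhc_II,
              peptides_I = peptides_I, peptides_II = peptides_II,
              antigen_protein = antigen_protein, self_peptides = self_peptides,
              ip_t = ip_t, ip_b_high = ip_b_high, ip_b_low = ip_b_low,
              templates_I = templates_I, templates_II = templates_II,
              template_b = template_b,
              pssms_I = pssms_I, pssms_II = pssms_II,
              thymus = thymus, rates = rates,
              prob_method = match.arg(prob_method),
              prob_slope = prob_slope, prob_midpoint = prob_midpoint,
              bias = bias, recognition_override = recognition_override,
              seed = as.integer(seed),
              stop_when_eradicated = isTRUE(stop_when_eradicated))
  class(cfg) <- "sim_config"
  cfg
}

#' Build a complete synthetic demonstration configuration
#'
#' Constructs every simulation input from the package's own fixture
#' generators: an immune-specific potential derived from a planted
#' synthetic structure campaign, fixture contact templates for one MHC-I
#' and one MHC-II allele plus an antibody template, synthetic PSSMs, a
#' random tumor antigen with its predicted epitopes, a random self-peptide
#' pool reduced to the 50 peptides most similar to each injected peptide,
#' and thymic thresholds calibrated so about half of a random repertoire
#' survives.
#'
#' @param seed Seed for all fixture construction.
#' @param ... Overrides forwarded to [sim_config()] (e.g. `duration`,
#'   `schedule`, `adjuvant`, `bias`, `recognition_override`).
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1, ...) {
  ip_t <- derive_potential(fixture_campaign(40, "planted", seed = seed + 11),
                           "IP_T", seed = seed + 12)
  ip_b <- derive_potential(
    fixture_campaign(40, "planted", seed = seed + 13, complex_kind = "antibody_antigen"),
    "IP_B_high", seed = seed + 14)

  tmpl_cx_I <- make_fixture_complex(12, 18, contact_fraction = 1, seed = seed + 21,
                                    id = "TMPL_I")
  tmpl_cx_II <- make_fixture_complex(12, 18, contact_fraction = 1, seed = seed + 22,
                                     id = "TMPL_II")
  tmpl_cx_B <- make_fixture_complex(12, 9, contact_fraction = 1, seed = seed + 23,
                                    complex_kind = "antibody_antigen", id = "TMPL_B")
  mhc_I <- c(HLA_FIX_A = withr::with_seed(seed + 31,
    paste(sample(aa_alphabet(), 9, TRUE), collapse = "")))
  mhc_II <- c(HLA_FIX_D = withr::with_seed(seed + 32,
    paste(sample(aa_alphabet(), 9, TRUE), collapse = "")))
  templates_I <- list(list(template_id = "TMPL_I", mhc_seq = mhc_I[[1]],
                           cm = build_contact_matrix(tmpl_cx_I)))
  templates_II <- list(list(template_id = "TMPL_II", mhc_seq = mhc_II[[1]],
                            cm = build_contact_matrix(tmpl_cx_II)))
  template_b <- build_contact_matrix(tmpl_cx_B)

  pssm_I <- make_fixture_pssm(names(mhc_I), 9, "I", seed = seed + 41)
  pssm_II <- make_fixture_pssm(names(mhc_II), 9, "II", seed = seed + 42)

  antigen_protein <- withr::with_seed(seed + 51,
    paste(sample(aa_alphabet(), 60, TRUE), collapse = ""))
  peptides_I <- predict_binders(antigen_protein, pssm_I, top_k = 1)$peptide
  peptides_II <- predict_binders(antigen_protein, pssm_II, top_k = 1)$peptide

  pool <- withr::with_seed(seed + 52, vapply(seq_len(200), function(i) {
    paste(sample(aa_alphabet(), 9, TRUE), collapse = "")
  }, character(1)))
  self_peptides <- unique(unlist(lapply(c(peptides_I, peptides_II), function(pep) {
    select_self_peptides(pool, pep, k = 50)
  })))

  thymus <- calibrate_thresholds(self_peptides, mhc_I, ip_t, templates_I,
                                 n_reference = 300, length = nrow(templates_I[[1]]$cm$m),
                                 seed = seed + 61)

  sim_config(mhc_I = mhc_I, mhc_II = mhc_II,
             peptides_I = peptides_I, peptides_II = peptides_II,
             antigen_protein = antigen_protein, self_peptides = self_peptides,
             ip_t = ip_t, ip_b_high = ip_b, ip_b_low = ip_b,
             templates_I = templates_I, templates_II = templates_II,
             template_b = template_b,
             pssms_I = list(pssm_I), pssms_II = list(pssm_II),
             thymus = thymus, seed = seed, ...)
}
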