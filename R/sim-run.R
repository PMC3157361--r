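# Agent type and state codes used by the lattice engine
TYPE_TH <- 1L; TYPE_TC <- 2L; TYPE_B <- 3L; TYPE_MA <- 4L; TYPE_DC <- 5L
ST_REST <- 1L; ST_ACTIVE <- 2L; ST_ANERGIC <- 3L; ST_MEMORY <- 4L; ST_PLASMA <- 5L

clamp01 <- function(p) pmin(pmax(p, 0), 1)

# effective probability under the bias multiplier / override
eff_prob <- function(p, cfg) {
  if (!is.null(cfg$recognition_override)) return(rep(cfg$recognition_override, length(p)))
  clamp01(p * cfg$bias)
}

#' Initialise the lattice state
#'
#' Dimensions the cubic lattice from the simulated volume, places the
#' initial cancer cells contiguously at the centre (a solid tumor),
#' seeds resting leukocytes at the configured densities on random sites,
#' generates random receptor repertoires, filters the T-cell clones
#' through thymic selection, and precomputes every clone's
#' potential-based recognition probabilities.
#'
#' @param cfg A `sim_config`.
#' @return An environment holding the mutable lattice state (molecule
#'   fields, agent vectors, clone tables, ledgers).  Consumed by
#'   [run_simulation()]; exposed for inspection and tests.
#' @export
sim_initialize <- function(cfg) {
  rates <- cfg$rates
  L <- max(3L, as.integer(round((cfg$volume_ul * rates$sites_per_ul)^(1 / 3))))
  nsites <- L^3
  st <- new.env(parent = emptyenv())
  st$L <- L
  st$nsites <- nsites
  st$antigen <- numeric(nsites)
  st$antibody <- numeric(nsites)
  st$il2 <- numeric(nsites)
  st$danger <- numeric(nsites)

  # solid tumor: fill the sites closest to the lattice centre
  ctr <- (L + 1) / 2
  coords <- expand.grid(x = seq_len(L), y = seq_len(L), z = seq_len(L))
  d2 <- (coords$x - ctr)^2 + (coords$y - ctr)^2 + (coords$z - ctr)^2
  ord <- order(d2)
  st$cancer <- integer(nsites)
  if (cfg$initial_cancer > 0) {
    n_full <- cfg$initial_cancer %% nsites
    base <- cfg$initial_cancer %/% nsites
    st$cancer <- st$cancer + base
    if (n_full > 0) st$cancer[ord[seq_len(n_full)]] <- st$cancer[ord[seq_len(n_full)]] + 1L
  }

  # clone tables with precomputed recognition probabilities -------------
  rec_len_t <- nrow(cfg$templates_I[[1]]$cm$m)
  rec_len_b <- nrow(cfg$template_b$m)
  n_by_type <- round(rates$density_per_ul * cfg$volume_ul)

  tcr <- generate_repertoire(max(n_by_type[["TC"]], 1), "TCR", rec_len_t,
                             seed = sample.int(2^31 - 1, 1))
  thr <- generate_repertoire(max(n_by_type[["TH"]], 1), "TCR", rec_len_t,
                             seed = sample.int(2^31 - 1, 1))
  tc_sel <- thymus_select(tcr, cfg$self_peptides, cfg$mhc_I, cfg$ip_t, cfg$templates_I,
                          cfg$thymus$positive_min, cfg$thymus$negative_max)
  th_sel <- thymus_select(thr, cfg$self_peptides, cfg$mhc_II, cfg$ip_t, cfg$templates_II,
                          cfg$thymus$positive_min, cfg$thymus$negative_max)
  bcr <- generate_repertoire(max(n_by_type[["B"]], 1), "BCR", rec_len_b,
                             seed = sample.int(2^31 - 1, 1))

  to_prob <- function(s) {
    score_to_probability(s, method = cfg$prob_method,
                         slope = cfg$prob_slope, midpoint = cfg$prob_midpoint)
  }
  max_prob_over <- function(seqs, alleles, templates, peptides, ip) {
    if (length(seqs) == 0 || length(peptides) == 0) return(numeric(0))
    best <- rep(0, length(seqs))
    for (a in seq_along(alleles)) {
      cm <- map_mhc_to_template(alleles[[a]], templates)
      for (pep in peptides) {
        s <- score_receptors(seqs, pmhc_ligand_seq(alleles[[a]], pep, cm), cm, ip)
        best <- pmax(best, to_prob(s))
      }
    }
    best
  }
  # cancer epitope per class-I allele: best predicted binder of the antigen
  cancer_eps <- lapply(cfg$pssms_I, function(p) predict_binders(cfg$antigen_protein, p, 1))
  p_present_cancer <- vapply(seq_along(cfg$pssms_I), function(i) {
    presentation_probability(cancer_eps[[i]]$score, cfg$pssms_I[[i]])
  }, numeric(1))

  tc_seqs <- tc_sel$seq
  st$tc_p_vac <- max_prob_over(tc_seqs, cfg$mhc_I, cfg$templates_I, cfg$peptides_I, cfg$ip_t)
  st$tc_p_cancer <- rep(0, length(tc_seqs))
  if (length(tc_seqs) > 0) {
    for (a in seq_along(cfg$mhc_I)) {
      cm <- map_mhc_to_template(cfg$mhc_I[[a]], cfg$templates_I)
      s <- score_receptors(tc_seqs,
                           pmhc_ligand_seq(cfg$mhc_I[[a]], cancer_eps[[a]]$peptide, cm),
                           cm, cfg$ip_t)
      st$tc_p_cancer <- pmax(st$tc_p_cancer,
                             p_present_cancer[a] * to_prob(s))
    }
  }
  st$th_p_vac <- max_prob_over(th_sel$seq, cfg$mhc_II, cfg$templates_II,
                               cfg$peptides_II, cfg$ip_t)

  # B-cell antigen recognition: IP_B variant chosen by the peptide's
  # glycine content relative to the surface frequency
  b_peps <- c(cfg$peptides_I, cfg$peptides_II)
  st$b_p_ag <- rep(0, nrow(bcr))
  for (pep in b_peps) {
    g_frac <- mean(strsplit(pep, "")[[1]] == "G")
    ip_b <- if (g_frac > 0.069) cfg$ip_b_high else cfg$ip_b_low
    s <- score_receptors(bcr$seq, pep, cfg$template_b, ip_b)
    st$b_p_ag <- pmax(st$b_p_ag, to_prob(s))
  }

  # APC presentation probabilities (PSSM-driven)
  pres_over <- function(pssms, peptides) {
    if (length(peptides) == 0) return(0)
    max(vapply(pssms, function(p) {
      max(vapply(peptides, function(pep) {
        presentation_probability(score_peptide(p, pep), p)
      }, numeric(1)))
    }, numeric(1)))
  }
  st$p_pres_I <- pres_over(cfg$pssms_I, cfg$peptides_I)
  st$p_pres_II <- pres_over(cfg$pssms_II, cfg$peptides_II)

  # agent arrays ---------------------------------------------------------
  n_init <- sum(n_by_type)
  cap <- max(256L, 4L * n_init)
  st$alive <- logical(cap); st$type <- integer(cap); st$state <- integer(cap)
  st$clone <- integer(cap); st$x <- integer(cap); st$y <- integer(cap)
  st$z <- integer(cap); st$has_ag <- logical(cap)
  st$pres_I <- logical(cap); st$pres_II <- logical(cap)
  st$divs <- integer(cap)
  st$n_used <- 0L

  seed_agents <- function(type, n, n_clones) {
    if (n < 1) return(invisible(NULL))
    idx <- st$n_used + seq_len(n)
    st$alive[idx] <- TRUE
    st$type[idx] <- type
    st$state[idx] <- ST_REST
    st$clone[idx] <- if (n_clones > 0) sample.int(n_clones, n, replace = TRUE) else 0L
    st$x[idx] <- sample.int(L, n, TRUE)
    st$y[idx] <- sample.int(L, n, TRUE)
    st$z[idx] <- sample.int(L, n, TRUE)
    st$n_used <- st$n_used + n
    invisible(NULL)
  }
  if (length(tc_seqs) == 0) {
    warning("no TC clone survived thymic selection; cellular response impossible",
            call. = FALSE)
  }
  seed_agents(TYPE_TH, n_by_type[["TH"]], length(st$th_p_vac))
  seed_agents(TYPE_TC, n_by_type[["TC"]], length(st$tc_p_vac))
  seed_agents(TYPE_B, n_by_type[["B"]], length(st$b_p_ag))
  seed_agents(TYPE_MA, n_by_type[["MA"]], 0L)
  seed_agents(TYPE_DC, n_by_type[["DC"]], 0L)
  # APCs and clone-less agents use clone 0; guard lookups with pmax
  st$clone[st$clone == 0L] <- 1L

  st$ledger <- list(births = 0L, deaths = 0L, cancer_born = 0L, cancer_killed = 0L)
  st
}

grow_capacity <- function(st, need) {
  cap <- length(st$alive)
  if (st$n_used + need <= cap) return(invisible(NULL))
  new_cap <- max(2L * cap, st$n_used + need)
  for (f in c("alive", "has_ag", "pres_I", "pres_II")) {
    v <- st[[f]]; length(v) <- new_cap; v[is.na(v)] <- FALSE; st[[f]] <- v
  }
  for (f in c("type", "state", "clone", "x", "y", "z", "divs")) {
    v <- st[[f]]; length(v) <- new_cap; v[is.na(v)] <- 0L; st[[f]] <- v
  }
  invisible(NULL)
}

spawn_agents <- function(st, type, state, clone, x, y, z, max_agents, divs = 0L) {
  n <- length(clone)
  divs <- rep_len(divs, n)
  if (n == 0) return(0L)
  room <- max_agents - sum(st$alive)
  if (room <= 0) return(0L)
  if (n > room) {
    keep <- seq_len(room)
    type <- type[keep]; state <- state[keep]; clone <- clone[keep]
    x <- x[keep]; y <- y[keep]; z <- z[keep]; divs <- divs[keep]
    n <- room
  }
  grow_capacity(st, n)
  idx <- st$n_used + seq_len(n)
  st$alive[idx] <- TRUE; st$type[idx] <- type; st$state[idx] <- state
  st$clone[idx] <- clone; st$x[idx] <- x; st$y[idx] <- y; st$z[idx] <- z
  st$has_ag[idx] <- FALSE; st$pres_I[idx] <- FALSE; st$pres_II[idx] <- FALSE
  st$divs[idx] <- divs
  st$n_used <- st$n_used + n
  n
}

site_of <- function(st, idx) {
  st$x[idx] + (st$y[idx] - 1L) * st$L + (st$z[idx] - 1L) * st$L^2
}

#' Advance the lattice by one 8-hour step
#'
#' Applies, in fixed order: scheduled injection (antigen, plus danger
#' signal when adjuvanted), cell movement (random walk; activated T-cells
#' walk preferentially toward the tumor centroid), phagocytosis
#' (unspecific for macrophages and dendritic cells, recognition-gated for
#' B-cells), MHC presentation, T-cell recognition of presented peptide
#' (activation with local danger signal, anergy without), clonal
#' expansion with memory formation, cytotoxic killing of cancer cells and
#' of presenting APCs, the humoral arm (helper-stimulated B-cells turning
#' plasma/memory, antibody secretion, antigen clearance), cancer
#' division, and molecule decay.
#'
#' @param st State environment from [sim_initialize()].
#' @param t Current step number (1-based).
#' @param cfg The `sim_config`.
#' @return The state environment, invisibly (mutated in place).
#' @export
sim_step <- function(st, t, cfg) {
  rates <- cfg$rates
  L <- st$L
  st$ledger <- list(births = 0L, deaths = 0L, cancer_born = 0L, cancer_killed = 0L)

  # (1) injection (schedule is 0-based: step s acts at loop iteration s + 1)
  if ((t - 1L) %in% cfg$schedule) {
    st$antigen <- st$antigen + rates$antigen_dose
    if (cfg$adjuvant) st$danger <- st$danger + rates$danger_dose
  }

  idx <- which(st$alive)
  n <- length(idx)
  if (n > 0) {
    ty <- st$type[idx]
    sta <- st$state[idx]
    cl <- st$clone[idx]
    is_tc <- ty == TYPE_TC; is_th <- ty == TYPE_TH; is_b <- ty == TYPE_B
    is_dc <- ty == TYPE_DC; is_ma <- ty == TYPE_MA
    is_t <- is_tc | is_th

    # (2) movement
    total_cancer <- sum(st$cancer)
    chemo <- is_t & sta == ST_ACTIVE & total_cancer > 0 &
      stats::runif(n) < rates$chemotaxis_p
    dx <- sample(c(-1L, 0L, 1L), n, TRUE)
    dy <- sample(c(-1L, 0L, 1L), n, TRUE)
    dz <- sample(c(-1L, 0L, 1L), n, TRUE)
    if (any(chemo)) {
      occ <- which(st$cancer > 0)
      w <- st$cancer[occ]
      cx <- ((occ - 1L) %% L) + 1L
      cy <- ((occ - 1L) %/% L) %% L + 1L
      cz <- (occ - 1L) %/% (L^2) + 1L
      gx <- sum(cx * w) / sum(w); gy <- sum(cy * w) / sum(w); gz <- sum(cz * w) / sum(w)
      ci <- idx[chemo]
      dx[chemo] <- sign(round(gx) - st$x[ci])
      dy[chemo] <- sign(round(gy) - st$y[ci])
      dz[chemo] <- sign(round(gz) - st$z[ci])
    }
    xx <- st$x[idx] + dx; xx[xx < 1L] <- 1L; xx[xx > L] <- L
    yy <- st$y[idx] + dy; yy[yy < 1L] <- 1L; yy[yy > L] <- L
    zz <- st$z[idx] + dz; zz[zz < 1L] <- 1L; zz[zz > L] <- L
    st$x[idx] <- xx; st$y[idx] <- yy; st$z[idx] <- zz

    sidx <- xx + (yy - 1L) * L + (zz - 1L) * L^2
    ag_here <- st$antigen[sidx] >= 1
    dg_here <- st$danger[sidx] > 0
    has_ag <- st$has_ag[idx]
    prI <- st$pres_I[idx]
    prII <- st$pres_II[idx]

    # (3) phagocytosis: APCs unspecific, B-cells recognition-gated
    if (any(ag_here)) {
      dc_ing <- is_dc & !has_ag & ag_here & stats::runif(n) < rates$p_phagocytosis
      ma_ing <- is_ma & !has_ag & ag_here & dg_here &
        stats::runif(n) < rates$p_phagocytosis
      b_cand <- which(is_b & sta == ST_REST & !has_ag & ag_here)
      b_ing <- logical(n)
      if (length(b_cand) > 0) {
        b_p <- eff_prob(st$b_p_ag[cl[b_cand]], cfg)
        b_ing[b_cand] <- stats::runif(length(b_cand)) < b_p
      }
      ing <- dc_ing | ma_ing | b_ing
      if (any(ing)) {
        has_ag[ing] <- TRUE
        st$has_ag[idx[ing]] <- TRUE
        dec <- tabulate(sidx[ing], nbins = st$nsites)
        st$antigen <- pmax(st$antigen - dec, 0)
      }
    }

    # (4) presentation
    if (any(has_ag)) {
      pI <- if (!is.null(cfg$recognition_override)) cfg$recognition_override else st$p_pres_I
      pII <- if (!is.null(cfg$recognition_override)) cfg$recognition_override else st$p_pres_II
      new_pI <- has_ag & !prI & is_dc & stats::runif(n) < pI
      new_pII <- has_ag & !prII & (is_dc | is_ma | is_b) & stats::runif(n) < pII
      prI <- prI | new_pI
      prII <- prII | new_pII
      st$pres_I[idx[new_pI]] <- TRUE
      st$pres_II[idx[new_pII]] <- TRUE
    }

    # (5) T-cell recognition of presented peptide: activation needs the
    # danger signal in the same site, recognition without it anergises
    if (any(prI) || any(prII)) {
      site_presI <- logical(st$nsites)
      site_presI[sidx[prI]] <- TRUE
      site_presII <- logical(st$nsites)
      site_presII[sidx[prII]] <- TRUE
      for (phase in 1:2) {
        p_clone <- if (phase == 1) st$tc_p_vac else st$th_p_vac
        if (length(p_clone) == 0) next
        cand <- which((if (phase == 1) is_tc & site_presI[sidx]
                       else is_th & site_presII[sidx]) &
                      (sta == ST_REST | sta == ST_MEMORY))
        if (length(cand) == 0) next
        p <- eff_prob(p_clone[cl[cand]], cfg)
        mem <- sta[cand] == ST_MEMORY
        if (any(mem)) p[mem] <- pmin(p[mem] * rates$memory_bonus, 1)
        hit <- cand[stats::runif(length(cand)) < p]
        if (length(hit) > 0) {
          new_state <- rep(ST_ANERGIC, length(hit))
          new_state[dg_here[hit]] <- ST_ACTIVE
          sta[hit] <- new_state
          st$state[idx[hit]] <- new_state
          act <- hit[dg_here[hit]]
          st$divs[idx[act]] <- rates$division_budget
        }
      }
    }

    # (6) clonal expansion of activated T-cells
    act_t <- which(is_t & sta == ST_ACTIVE)
    if (length(act_t) > 0) {
      p_d <- rates$p_duplicate *
        (1 + rates$il2_boost * (st$il2[sidx[act_t]] > 0))
      dup <- act_t[st$divs[idx[act_t]] > 0L & stats::runif(length(act_t)) < p_d]
      if (length(dup) > 0) {
        di <- idx[dup]
        st$divs[di] <- st$divs[di] - 1L
        child_state <- rep(ST_ACTIVE, length(di))
        child_state[stats::runif(length(di)) < rates$p_memory] <- ST_MEMORY
        born <- spawn_agents(st, st$type[di], child_state, st$clone[di],
                             st$x[di], st$y[di], st$z[di], rates$max_agents,
                             divs = st$divs[di])
        st$ledger$births <- st$ledger$births + born
      }
      th_act <- act_t[is_th[act_t]]
      if (length(th_act) > 0) {
        st$il2 <- st$il2 +
          tabulate(sidx[th_act], nbins = st$nsites) * rates$il2_per_th
      }
    }

    # (7) cytotoxic kill: cancer cells, then presenting APCs
    tc_act <- which(is_tc & sta == ST_ACTIVE)
    if (length(tc_act) > 0) {
      ti <- tc_act[st$cancer[sidx[tc_act]] > 0]
      if (length(ti) > 0) {
        p_k <- eff_prob(st$tc_p_cancer[cl[ti]], cfg)
        kills <- stats::rbinom(length(ti), st$cancer[sidx[ti]], p_k)
        if (sum(kills) > 0) {
          agg <- rowsum(kills, sidx[ti])
          sites <- as.integer(rownames(agg))
          before <- st$cancer[sites]
          st$cancer[sites] <- pmax(before - as.integer(agg), 0L)
          st$ledger$cancer_killed <- st$ledger$cancer_killed +
            sum(before - st$cancer[sites])
        }
      }
      site_tc <- logical(st$nsites)
      site_tc[sidx[tc_act]] <- TRUE
      apc <- which((prI | prII) & (is_dc | is_ma | is_b) & site_tc[sidx])
      if (length(apc) > 0) {
        die <- apc[stats::runif(length(apc)) < rates$p_kill_apc]
        if (length(die) > 0) {
          st$alive[idx[die]] <- FALSE
          st$ledger$deaths <- st$ledger$deaths + length(die)
        }
      }
    }

    # (7b) contraction: activated effectors die at a small per-step rate
    eff <- which(is_t & sta == ST_ACTIVE & st$alive[idx])
    if (length(eff) > 0) {
      dead_eff <- eff[stats::runif(length(eff)) < rates$p_active_death]
      if (length(dead_eff) > 0) {
        st$alive[idx[dead_eff]] <- FALSE
        st$ledger$deaths <- st$ledger$deaths + length(dead_eff)
      }
    }

    # (8) humoral arm
    alive_now <- st$alive[idx]
    th_on <- which(alive_now & is_th & sta == ST_ACTIVE)
    b_pres <- which(alive_now & is_b & prII & sta == ST_REST)
    if (length(th_on) > 0 && length(b_pres) > 0) {
      th_act_site <- logical(st$nsites)
      th_act_site[sidx[th_on]] <- TRUE
      b_stim <- b_pres[th_act_site[sidx[b_pres]] &
                       stats::runif(length(b_pres)) < rates$p_b_stimulation]
      if (length(b_stim) > 0) {
        bi <- idx[b_stim]
        sta[b_stim] <- ST_PLASMA
        st$state[bi] <- ST_PLASMA
        born <- spawn_agents(st, rep(TYPE_B, length(bi)), rep(ST_MEMORY, length(bi)),
                             st$clone[bi], st$x[bi], st$y[bi], st$z[bi],
                             rates$max_agents)
        st$ledger$births <- st$ledger$births + born
      }
    }
    plasma <- which(st$alive[idx] & is_b & sta == ST_PLASMA)
    if (length(plasma) > 0) {
      st$antibody <- st$antibody +
        tabulate(sidx[plasma], nbins = st$nsites) * rates$antibody_per_plasma
      dead_pl <- plasma[stats::runif(length(plasma)) < rates$p_plasma_death]
      if (length(dead_pl) > 0) {
        st$alive[idx[dead_pl]] <- FALSE
        st$ledger$deaths <- st$ledger$deaths + length(dead_pl)
      }
    }

    # (8b) presenting APCs lose their peptide-MHC complexes over time
    pres_now <- which(st$alive[idx] & (prI | prII))
    if (length(pres_now) > 0) {
      stopp <- pres_now[stats::runif(length(pres_now)) < rates$p_stop_present]
      if (length(stopp) > 0) {
        ii <- idx[stopp]
        st$pres_I[ii] <- FALSE
        st$pres_II[ii] <- FALSE
        st$has_ag[ii] <- FALSE
      }
    }
    if (any(st$antibody > 0)) {
      st$antigen <- pmax(st$antigen - rates$antigen_clear_per_antibody * st$antibody, 0)
    }
  }

  # (9) cancer division
  occ <- which(st$cancer > 0)
  if (length(occ) > 0) {
    born <- stats::rbinom(length(occ), st$cancer[occ], rates$cancer_division_p)
    st$cancer[occ] <- st$cancer[occ] + born
    st$ledger$cancer_born <- st$ledger$cancer_born + sum(born)
  }

  # (10) molecule decay with floor at zero
  st$antigen <- st$antigen * rates$decay_antigen
  st$antibody <- st$antibody * rates$decay_antibody
  st$il2 <- st$il2 * rates$decay_il2
  st$danger <- st$danger * rates$decay_danger
  fl <- rates$molecule_floor
  st$antigen[st$antigen < fl] <- 0
  st$antibody[st$antibody < fl] <- 0
  st$il2[st$il2 < fl] <- 0
  st$danger[st$danger < fl] <- 0

  invisible(st)
}

sim_record <- function(st) {
  idx <- which(st$alive)
  ty <- st$type[idx]; sta <- st$state[idx]
  cnt <- function(type, state) sum(ty == type & sta == state)
  c(cancer = sum(st$cancer),
    TH_resting = cnt(TYPE_TH, ST_REST), TH_active = cnt(TYPE_TH, ST_ACTIVE),
    TH_anergic = cnt(TYPE_TH, ST_ANERGIC), TH_memory = cnt(TYPE_TH, ST_MEMORY),
    TC_resting = cnt(TYPE_TC, ST_REST), TC_active = cnt(TYPE_TC, ST_ACTIVE),
    TC_anergic = cnt(TYPE_TC, ST_ANERGIC), TC_memory = cnt(TYPE_TC, ST_MEMORY),
    B_resting = cnt(TYPE_B, ST_REST), B_plasma = cnt(TYPE_B, ST_PLASMA),
    B_memory = cnt(TYPE_B, ST_MEMORY),
    MA_total = sum(ty == TYPE_MA), DC_total = sum(ty == TYPE_DC),
    DC_presenting_I = sum(ty == TYPE_DC & st$pres_I[idx]),
    DC_presenting_II = sum(ty == TYPE_DC & st$pres_II[idx]),
    MA_presenting_II = sum(ty == TYPE_MA & st$pres_II[idx]),
    B_presenting_II = sum(ty == TYPE_B & st$pres_II[idx]),
    immune_total = length(idx),
    antigen = sum(st$antigen), antibody = sum(st$antibody),
    il2 = sum(st$il2), danger = sum(st$danger),
    births = st$ledger$births, deaths = st$ledger$deaths,
    cancer_born = st$ledger$cancer_born, cancer_killed = st$ledger$cancer_killed)
}

#' Run a full vaccination simulation
#'
#' Initialises the lattice and advances it for `cfg$duration` 8-hour
#' steps, recording per-step counts for every cell population and
#' activation state, molecule totals, and birth/death ledgers.  The run
#' is fully determined by the configuration and its seed.  If the tumor
#' is eradicated and `stop_when_eradicated` is set, stepping halts and
#' the terminal counts are carried forward so the series always has
#' `duration + 1` rows.
#'
#' @param cfg A `sim_config` (see [demo_config()] for a synthetic one).
#' @return Object of class `immune_sim`: list with tibble `series`
#'   (step 0..duration), `final_cancer`, `eradicated_step` (NA if
#'   never), and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- demo_config(seed = 1, duration = 30)
#' sim <- run_simulation(cfg)
#' sim$final_cancer
#' }
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    st <- sim_initialize(cfg)
    st$ledger <- list(births = 0L, deaths = 0L, cancer_born = 0L, cancer_killed = 0L)
    rec <- matrix(NA_real_, cfg$duration + 1L, length(sim_record(st)))
    colnames(rec) <- names(sim_record(st))
    rec[1, ] <- sim_record(st)
    eradicated_step <- NA_integer_
    last <- cfg$duration
    for (t in seq_len(cfg$duration)) {
      sim_step(st, t, cfg)
      rec[t + 1L, ] <- sim_record(st)
      if (is.na(eradicated_step) && sum(st$cancer) == 0) eradicated_step <- t
      if (cfg$stop_when_eradicated && !is.na(eradicated_step)) {
        last <- t
        break
      }
      # quiescence: no stimulus left anywhere and none to come -- only
      # tumor growth remains, so advance it directly
      if (t %% 10L == 0L && t > max(c(cfg$schedule, -1L)) + 1L &&
          sum(st$antigen) == 0 && sum(st$danger) == 0 &&
          sum(st$il2) == 0 && sum(st$antibody) == 0) {
        ai <- which(st$alive)
        if (!any(st$has_ag[ai]) && !any(st$pres_I[ai]) && !any(st$pres_II[ai]) &&
            !any(st$state[ai] == ST_ACTIVE) && !any(st$state[ai] == ST_PLASMA)) {
          base_row <- rec[t + 1L, ]
          base_row[c("births", "deaths", "cancer_born", "cancer_killed")] <- 0
          for (tt in seq_len(cfg$duration - t)) {
            occ <- which(st$cancer > 0)
            if (length(occ) > 0) {
              born <- stats::rbinom(length(occ), st$cancer[occ],
                                    cfg$rates$cancer_division_p)
              st$cancer[occ] <- st$cancer[occ] + born
              base_row["cancer_born"] <- sum(born)
            } else base_row["cancer_born"] <- 0
            base_row["cancer"] <- sum(st$cancer)
            rec[t + tt + 1L, ] <- base_row
          }
          last <- cfg$duration
          break
        }
      }
    }
    if (last < cfg$duration) {
      carry <- rec[last + 1L, ]
      carry[c("births", "deaths", "cancer_born", "cancer_killed")] <- 0
      for (t in (last + 1L):cfg$duration) rec[t + 1L, ] <- carry
    }
    series <- tibble::as_tibble(rec)
    series$step <- 0:cfg$duration
    series <- dplyr::relocate(series, "step")
    structure(list(series = series,
                   final_cancer = series$cancer[nrow(series)],
                   eradicated_step = eradicated_step,
                   config = cfg),
              class = "immune_sim")
  })
}

#' @export
print.immune_sim <- function(x, ...) {
  cat(sprintf("<immune_sim: %d steps, cancer %d -> %d%s>\n",
              x$config$duration, x$config$initial_cancer, x$final_cancer,
              if (!is.na(x$eradicated_step))
                sprintf(" (eradicated at step %d)", x$eradicated_step) else ""))
  invisible(x)
}

#' Tidy a simulation into long format
#'
#' @param x An `immune_sim`.
#' @param ... Unused.
#' @return Tibble with columns `step`, `population`, `count` (cell
#'   populations and molecule totals; ledger columns excluded).
#' @method tidy immune_sim
#' @export
tidy.immune_sim <- function(x, ...) {
  drop <- c("births", "deaths", "cancer_born", "cancer_killed")
  x$series |>
    dplyr::select(-dplyr::all_of(drop)) |>
    tidyr::pivot_longer(-"step", names_to = "population", values_to = "count")
}

#' One-row summary of a simulation run
#'
#' @param x An `immune_sim`.
#' @param ... Unused.
#' @return Tibble: initial and final cancer counts, eradication step,
#'   peak active T-cell counts, outcome.
#' @method glance immune_sim
#' @export
glance.immune_sim <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    initial_cancer = x$config$initial_cancer,
    final_cancer = x$final_cancer,
    eradicated_step = x$eradicated_step,
    peak_tc_active = max(s$TC_active),
    peak_th_active = max(s$TH_active),
    outcome = classify_outcome(x)
  )
}

#' Plot population trajectories of a run
#'
#' @param object An `immune_sim`.
#' @param populations Which series columns to draw.
#' @param ... Unused.
#' @return A ggplot with one facet per population.
#' @method autoplot immune_sim
#' @export
autoplot.immune_sim <- function(object,
                                populations = c("cancer", "TC_active", "TH_active",
                                                "B_plasma", "DC_presenting_I",
                                                "MA_presenting_II"),
                                ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$population %in% populations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "step (8 h)", y = "count") +
    ggplot2::theme_minimal()
}
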