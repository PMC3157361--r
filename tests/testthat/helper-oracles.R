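# Independent brute-force oracles, deliberately naive implementations.

# all receptor x ligand residue pairs within cutoff, via explicit loops
bf_interface <- function(cx, cutoff = 8.0) {
  res <- cx$residues
  rec <- res[res$role == "receptor", ]
  lig <- res[res$role == "ligand", ]
  out <- NULL
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        out <- rbind(out, data.frame(receptor_index = rec$seq_index[i],
                                     receptor_aa = rec$aa[i],
                                     ligand_index = lig$seq_index[j],
                                     ligand_aa = lig$aa[j],
                                     distance = d))
      }
    }
  }
  if (is.null(out)) data.frame(receptor_index = integer(0), receptor_aa = character(0),
                               ligand_index = integer(0), ligand_aa = character(0),
                               distance = numeric(0)) else out
}

bf_count_pairs <- function(structures, cutoff = 8.0) {
  m <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (cx in structures) {
    pairs <- bf_interface(cx, cutoff)
    for (k in seq_len(nrow(pairs))) {
      m[pairs$receptor_aa[k], pairs$ligand_aa[k]] <-
        m[pairs$receptor_aa[k], pairs$ligand_aa[k]] + 1
    }
  }
  m
}

# AUC as the fraction of correctly ordered (pos, neg) pairs, ties half
bf_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# mean potential value over contacts, explicit double loop
bf_score <- function(receptor_seq, ligand_seq, cm, ip) {
  rec <- strsplit(receptor_seq, "")[[1]]
  lig <- strsplit(ligand_seq, "")[[1]]
  tot <- 0
  nc <- 0
  for (i in seq_len(nrow(cm$m))) {
    for (j in seq_len(ncol(cm$m))) {
      if (cm$m[i, j] == 1) {
        tot <- tot + ip$matrix[rec[i], lig[j]]
        nc <- nc + 1
      }
    }
  }
  tot / nc
}

# a 20x20 potential with chosen entries planted on a zero background
test_potential <- function(entries, variant = "IP_T") {
  m <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  ipvax:::new_interaction_potential(m, variant, max_before_norm = max(m))
}

# minimal immune_sim stand-in for outcome/reactiveness arithmetic
fake_sim <- function(final, initial = 100, duration = 10) {
  structure(list(final_cancer = final,
                 eradicated_step = if (final == 0) 1L else NA_integer_,
                 series = tibble::tibble(step = 0:1, cancer = c(initial, final)),
                 config = list(duration = duration, initial_cancer = initial)),
            class = "immune_sim")
}
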