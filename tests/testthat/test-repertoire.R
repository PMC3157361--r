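test_that("repertoire generation is uniform, sized and reproducible", {
  big <- generate_repertoire(15000, "TCR", length = 12, seed = 1)
  expect_equal(nrow(big), 15000)
  expect_identical(big, generate_repertoire(15000, "TCR", length = 12, seed = 1))
  other <- generate_repertoire(15000, "TCR", length = 12, seed = 2)
  expect_false(identical(big$seq, other$seq))

  singles <- generate_repertoire(2000, "BCR", length = 1, seed = 3)
  expect_setequal(unique(singles$seq), aa_alphabet())
})

test_that("batch receptor scoring agrees with the scalar scorer", {
  cx <- make_fixture_complex(4, 6, contact_fraction = 1, seed = 4)
  cm <- build_contact_matrix(cx)
  ip <- synthetic_general_potential()
  reps <- generate_repertoire(25, "TCR", length = 4, seed = 5)
  lig <- paste(rep("L", 6), collapse = "")
  batch <- score_receptors(reps$seq, lig, cm, ip)
  single <- vapply(reps$seq, function(s) score_interaction(s, lig, cm, ip),
                   numeric(1), USE.NAMES = FALSE)
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("thymic selection is a pure, order-preserving filter", {
  cx <- make_fixture_complex(4, 12, contact_fraction = 1, seed = 6)
  templates <- list(list(template_id = "T", mhc_seq = "GGGGGGGGG",
                         cm = build_contact_matrix(cx)))
  ip <- test_potential(list(list("A", "G", 1.0)))
  rep <- generate_repertoire(50, "TCR", length = 4, seed = 7)
  self <- c("GGG", "GGG")

  all_kept <- thymus_select(rep, self, c(M = "GGGGGGGGG"), ip, templates,
                            positive_min = -Inf, negative_max = Inf)
  expect_equal(all_kept$seq, rep$seq)

  # an engineered strongly self-reactive clone is eliminated
  rep2 <- rep
  rep2$seq[10] <- "AAAA"   # scores 1.0 against the all-G self background
  kept <- thymus_select(rep2, self, c(M = "GGGGGGGGG"), ip, templates,
                        positive_min = -Inf, negative_max = 0.9)
  expect_false("AAAA" %in% kept$seq)
  expect_true(all(kept$seq %in% rep2$seq))
  expect_identical(kept$seq, rep2$seq[rep2$seq %in% kept$seq])
})

test_that("selection thresholds act monotonically", {
  cx <- make_fixture_complex(4, 12, contact_fraction = 1, seed = 8)
  templates <- list(list(template_id = "T", mhc_seq = "AAAAAAAAA",
                         cm = build_contact_matrix(cx)))
  ip <- synthetic_general_potential()
  rep <- generate_repertoire(80, "TCR", length = 4, seed = 9)
  self_small <- c("AAA", "LLL")
  self_big <- c(self_small, "VVV", "III", "FFF")

  n_at <- function(neg_max, self) {
    nrow(thymus_select(rep, self, c(M = "AAAAAAAAA"), ip, templates,
                       positive_min = -Inf, negative_max = neg_max))
  }
  expect_lte(n_at(0.1, self_small), n_at(0.3, self_small))
  expect_lte(n_at(0.3, self_small), n_at(0.6, self_small))
  # growing the self set can only eliminate more clones
  expect_lte(n_at(0.3, self_big), n_at(0.3, self_small))

  n_pos <- function(pos_min) {
    nrow(thymus_select(rep, self_small, c(M = "AAAAAAAAA"), ip, templates,
                       positive_min = pos_min, negative_max = Inf))
  }
  expect_gte(n_pos(-Inf), n_pos(0))
  expect_gte(n_pos(0), n_pos(0.5))
})

test_that("self-overlapping tumor epitopes lose reactivity after selection", {
  # tumor epitope equals a self peptide: clones reactive to it are culled,
  # so the survivor set's mean anti-tumor score cannot exceed the input's
  cx <- make_fixture_complex(4, 12, contact_fraction = 1, seed = 10)
  templates <- list(list(template_id = "T", mhc_seq = "GGGGGGGGG",
                         cm = build_contact_matrix(cx)))
  ip <- synthetic_general_potential()
  rep <- generate_repertoire(200, "TCR", length = 4, seed = 11)
  tumor_pep <- "III"
  cm <- templates[[1]]$cm
  lig <- pmhc_ligand_seq("GGGGGGGGG", tumor_pep, cm)
  pre <- mean(score_receptors(rep$seq, lig, cm, ip))
  kept <- thymus_select(rep, tumor_pep, c(M = "GGGGGGGGG"), ip, templates,
                        positive_min = -Inf, negative_max = 0.2)
  expect_gt(nrow(kept), 0)
  post <- mean(score_receptors(kept$seq, lig, cm, ip))
  expect_lte(post, pre)
})

test_that("calibrated thresholds keep roughly the target fraction alive", {
  cx <- make_fixture_complex(4, 12, contact_fraction = 1, seed = 12)
  templates <- list(list(template_id = "T", mhc_seq = "AAAAAAAAA",
                         cm = build_contact_matrix(cx)))
  ip <- synthetic_general_potential()
  self <- c("AAA", "GGG", "LLL")
  th <- calibrate_thresholds(self, c(M = "AAAAAAAAA"), ip, templates,
                             n_reference = 400, target_survival = 0.5,
                             length = 4, seed = 13)
  rep <- generate_repertoire(400, "TCR", length = 4, seed = 14)
  kept <- thymus_select(rep, self, c(M = "AAAAAAAAA"), ip, templates,
                        th$positive_min, th$negative_max)
  expect_gt(nrow(kept) / nrow(rep), 0.3)
  expect_lt(nrow(kept) / nrow(rep), 0.7)
})

test_that("repertoires round-trip through FASTA", {
  rep <- generate_repertoire(20, "BCR", length = 8, seed = 15)
  tf <- tempfile(fileext = ".fasta")
  write_repertoire_fasta(rep, tf)
  back <- read_fasta_sequences(tf)
  expect_equal(back$seq, rep$seq)
  expect_equal(back$receptor_id, rep$receptor_id)
})
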