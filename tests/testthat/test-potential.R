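test_that("decoys randomise only the ligand sequence", {
  cx <- make_fixture_complex(5, 5, contact_fraction = 0.8, seed = 3)
  all_a <- surface_composition(stats::setNames(c(1, rep(0, 19)), aa_alphabet()))
  withr::with_seed(1, {
    d <- make_decoy(cx, all_a)
  })
  expect_identical(d$residues[, c("x", "y", "z")], cx$residues[, c("x", "y", "z")])
  expect_identical(d$residues$aa[d$residues$role == "receptor"],
                   cx$residues$aa[cx$residues$role == "receptor"])
  expect_true(all(d$residues$aa[d$residues$role == "ligand"] == "A"))
})

test_that("decoy ligand composition converges to the sampling distribution", {
  cx <- make_fixture_complex(3, 10, contact_fraction = 1, seed = 4)
  comp <- surface_composition()
  n_dec <- 10000
  withr::with_seed(2, {
    draws <- unlist(lapply(seq_len(n_dec), function(i) {
      d <- make_decoy(cx, comp)
      d$residues$aa[d$residues$role == "ligand"]
    }))
  })
  n_tot <- length(draws)
  freq <- table(factor(draws, levels = aa_alphabet())) / n_tot
  se <- sqrt(comp * (1 - comp) / n_tot)
  expect_true(all(abs(freq - comp) <= 3 * se + 1e-12))
})

test_that("pair counting matches hand enumeration and brute force", {
  res <- tibble::tibble(
    chain_id = c("R", "R", "L", "L", "L"),
    role = c("receptor", "receptor", "ligand", "ligand", "ligand"),
    aa = c("A", "G", "G", "L", "G"),
    seq_index = c(1L, 2L, 1L, 2L, 3L),
    x = c(0, 30, 0, 3, 30), y = c(0, 0, 0, 0, 0), z = c(0, 0, 5, 5, 5))
  cx <- new_complex_structure("hand", res)
  pc <- count_pairs(list(cx))
  expect_equal(pc$counts["A", "G"], 1)
  expect_equal(pc$counts["A", "L"], 1)
  expect_equal(pc$counts["G", "G"], 1)
  expect_equal(sum(pc$counts), 3)

  withr::with_seed(20, {
    cxs <- lapply(1:10, function(i) {
      make_fixture_complex(sample(2:6, 1), sample(2:6, 1),
                           contact_fraction = stats::runif(1),
                           seed = sample.int(1e6, 1))
    })
  })
  expect_equal(unclass(count_pairs(cxs)$counts), bf_count_pairs(cxs),
               ignore_attr = TRUE)
  shuffled <- count_pairs(rev(cxs))
  expect_equal(shuffled$counts, count_pairs(cxs)$counts)
})

test_that("potential derivation recovers a planted pair preference", {
  cxs <- lapply(1:30, function(i) {
    make_fixture_complex(4, 4, "AAAA", "AAAA", contact_fraction = 1, seed = i)
  })
  ip <- derive_potential(cxs, "IP_T", comp = uniform_composition(), seed = 1)
  expect_identical(max(ip$matrix), 1)
  idx <- which(ip$matrix == 1, arr.ind = TRUE)
  expect_equal(nrow(idx), 1)
  expect_equal(rownames(ip$matrix)[idx[1, 1]], "A")
  expect_equal(colnames(ip$matrix)[idx[1, 2]], "A")

  # stability: more decoys per structure keep the same argmax
  ip10 <- derive_potential(cxs, "IP_T", comp = uniform_composition(),
                           decoys_per_structure = 10, seed = 2)
  expect_equal(which.max(ip10$matrix), which.max(ip$matrix))
})

test_that("null-composition sets carry no systematic signal", {
  comp <- surface_composition()
  null_set <- fixture_campaign(200, "null", seed = 31, comp = comp)
  ip_null <- derive_potential(null_set, "IP_T", comp = comp, seed = 32)
  raw_null <- ip_null$matrix * ip_null$max_before_norm
  # the signed total count difference has mean zero under the null
  expect_lt(abs(sum(raw_null)), 1)

  planted <- fixture_campaign(200, "planted", seed = 33, comp = comp)
  ip_pl <- derive_potential(planted, "IP_T", comp = comp, seed = 34)
  expect_gt(ip_pl$max_before_norm, 3 * ip_null$max_before_norm)
})

test_that("glycine fraction counts distinct ligand interface residues", {
  cx <- make_fixture_complex(4, 4, "AAAA", "GGAL", contact_fraction = 1, seed = 6)
  expect_equal(glycine_fraction(cx), 0.5)
  cx0 <- make_fixture_complex(3, 3, "AAA", "ALV", contact_fraction = 1, seed = 7)
  expect_equal(glycine_fraction(cx0), 0)
  empty <- make_fixture_complex(3, 3, contact_fraction = 0, seed = 8)
  expect_error(glycine_fraction(empty), "empty interface")
})

test_that("glycine split partitions exhaustively with ties to the low set", {
  mk_frac <- function(frac, seed) {
    n <- 40
    n_g <- round(frac * n)
    lig <- paste(c(rep("G", n_g), rep("A", n - n_g)), collapse = "")
    make_fixture_complex(n, n, ligand_seq = lig, contact_fraction = 1,
                         seed = seed, complex_kind = "antibody_antigen")
  }
  set <- list(mk_frac(0.05, 1), mk_frac(0.25, 2), mk_frac(0.5, 3))
  sp <- split_by_glycine(set, threshold = 0.25)
  expect_equal(length(sp$low), 2)   # 0.05 and the tie at 0.25
  expect_equal(length(sp$high), 1)
  expect_setequal(c(vapply(sp$low, function(x) x$id, ""),
                    vapply(sp$high, function(x) x$id, "")),
                  vapply(set, function(x) x$id, ""))
  expect_error(split_by_glycine(list(make_fixture_complex(2, 2, seed = 1))),
               "antibody_antigen")
  empty <- split_by_glycine(list())
  expect_equal(length(empty$high) + length(empty$low), 0)
})

test_that("contact matrices mirror the interface exactly", {
  cx <- make_fixture_complex(2, 2, contact_fraction = 1, seed = 9)
  cm <- build_contact_matrix(cx)
  expect_equal(dim(cm$m), c(2, 2))
  expect_equal(sum(cm$m), nrow(extract_interface(cx)))
  expect_true(all(cm$m %in% c(0, 1)))

  cx5 <- make_fixture_complex(5, 5, contact_fraction = 1, seed = 10)
  cm5 <- build_contact_matrix(cx5)
  expect_equal(sum(cm5$m), nrow(extract_interface(cx5)))

  no_contact <- make_fixture_complex(3, 3, contact_fraction = 0, seed = 11)
  expect_error(build_contact_matrix(no_contact), "empty interface")
})

test_that("interaction scores equal the mean potential over contacts", {
  cm <- structure(list(template_id = "t", m = matrix(1L, 2, 2)),
                  class = "contact_matrix")
  ip <- test_potential(list(list("A", "G", 1.0), list("A", "L", 0.5),
                            list("G", "G", -0.2), list("G", "L", 0.1)))
  expect_equal(score_interaction("AG", "GL", cm, ip), 0.35)

  zero_ip <- test_potential(list())
  expect_equal(score_interaction("AG", "GL", cm, zero_ip), 0)

  single <- structure(list(template_id = "t", m = matrix(1L, 1, 1)),
                      class = "contact_matrix")
  expect_equal(score_interaction("A", "G", single, ip), 1.0)

  # all-zero rows/columns of the template never change the score
  cm_pad <- structure(list(template_id = "t",
                           m = rbind(cbind(cm$m, 0L), 0L)),
                      class = "contact_matrix")
  expect_equal(score_interaction("AGA", "GLA", cm_pad, ip),
               score_interaction("AG", "GL", cm, ip))

  expect_error(score_interaction("AX", "GL", cm, ip), "non-standard")
})

test_that("longer sequences are scored over the best window", {
  cm <- structure(list(template_id = "t", m = matrix(1L, 1, 1)),
                  class = "contact_matrix")
  ip <- test_potential(list(list("W", "F", 1.0)))
  # best window pairs the W with the F regardless of flanking residues
  expect_equal(score_interaction("AWA", "GFG", cm, ip), 1.0)
  expect_equal(score_interaction("AAA", "GGG", cm, ip), 0)
})

test_that("random interaction scores match the brute-force oracle", {
  withr::with_seed(40, {
    for (rep in 1:30) {
      nr <- sample(2:6, 1); nl <- sample(2:6, 1)
      m <- matrix(rbinom(nr * nl, 1, 0.5), nr, nl)
      if (sum(m) == 0) m[1, 1] <- 1L
      cm <- structure(list(template_id = "t", m = m), class = "contact_matrix")
      mat <- matrix(rnorm(400), 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
      ip <- ipvax:::new_interaction_potential(mat, "IP_T", max(mat))
      rseq <- paste(sample(aa_alphabet(), nr, TRUE), collapse = "")
      lseq <- paste(sample(aa_alphabet(), nl, TRUE), collapse = "")
      expect_equal(score_interaction(rseq, lseq, cm, ip),
                   bf_score(rseq, lseq, cm, ip), tolerance = 1e-12)
    }
  })
})

test_that("score-to-probability clamps by default and stays monotone", {
  expect_equal(score_to_probability(0.35), 0.35)
  expect_equal(score_to_probability(-0.4), 0)
  expect_equal(score_to_probability(1.0), 1.0)
  grid <- seq(-1, 1, by = 0.05)
  for (m in c("clamp", "logistic")) {
    p <- score_to_probability(grid, method = m)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("MHC sequences map to the highest-identity template", {
  cx1 <- make_fixture_complex(3, 3, contact_fraction = 1, seed = 12, id = "T1")
  cx2 <- make_fixture_complex(3, 3, contact_fraction = 0.67, seed = 13, id = "T2")
  lib <- list(
    list(template_id = "T1", mhc_seq = "AAAAAAAAAA", cm = build_contact_matrix(cx1)),
    list(template_id = "T2", mhc_seq = "GGGGGGGGGG", cm = build_contact_matrix(cx2))
  )
  expect_identical(map_mhc_to_template("AAAAAAAAAA", lib)$template_id, "T1")
  # 90% identity to T1, 0% to T2
  expect_identical(map_mhc_to_template("AAAAAAAAAG", lib)$template_id, "T1")
  # 90% to T2, 10% to T1
  expect_identical(map_mhc_to_template("AGGGGGGGGG", lib)$template_id, "T2")
  expect_identical(map_mhc_to_template("AAAA", lib[2])$template_id, "T2")
  expect_error(map_mhc_to_template("AAAA", list()), "empty")
})

test_that("potential and contact serialisation round-trips", {
  cxs <- fixture_campaign(20, "planted", seed = 14)
  ip <- derive_potential(cxs, "IP_B", seed = 15)
  tf <- tempfile(fileext = ".tsv")
  write_potential(ip, tf)
  ip2 <- read_potential(tf)
  expect_equal(ip2$matrix, ip$matrix, tolerance = 1e-9)
  expect_identical(ip2$variant, "IP_B")

  cm <- build_contact_matrix(cxs[[1]])
  tf2 <- tempfile(fileext = ".tsv")
  write_contact_matrix(cm, tf2)
  cm2 <- read_contact_matrix(tf2)
  expect_identical(cm2$m, cm$m)
  expect_identical(cm2$template_id, cm$template_id)
})
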