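test_that("PDB parsing keeps mapped chains, roles and standard residues", {
  pdb <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  LEU A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  TRP B   1       0.000   5.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  MSE B   2       3.800   5.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  cx <- parse_structure(pdb, c(A = "receptor", B = "ligand"))
  expect_s3_class(cx, "complex_structure")
  expect_equal(nrow(cx$residues), 5)
  expect_equal(length(unique(cx$residues$chain_id)), 2)
  # MSE maps to its parent methionine; alphabet stays closed
  expect_equal(cx$residues$aa[cx$residues$chain_id == "B"], c("W", "M"))
  expect_true(all(cx$residues$aa %in% aa_alphabet()))
})

test_that("parsing errors on chains without usable C-alpha residues", {
  het_only <- paste(
    "HETATM    1  C1  NAG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_error(parse_structure(het_only, c(A = "receptor")), "C-alpha")
  pdb <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  expect_error(parse_structure(pdb, c(A = "receptor", Z = "ligand")), "absent")
})

test_that("fixture complexes round-trip through PDB text", {
  cx <- make_fixture_complex(6, 5, contact_fraction = 0.6, seed = 7)
  cx2 <- parse_structure(write_pdb(cx), c(R = "receptor", L = "ligand"),
                         id = cx$id)
  expect_identical(cx$residues$aa, cx2$residues$aa)
  expect_identical(cx$residues$role, cx2$residues$role)
  expect_lt(max(abs(as.matrix(cx$residues[, c("x", "y", "z")]) -
                    as.matrix(cx2$residues[, c("x", "y", "z")]))), 0.001)
})

test_that("the 8 Angstrom interface boundary is inclusive", {
  mk <- function(lig_x) {
    new_complex_structure("b", tibble::tibble(
      chain_id = c("R", "L"), role = c("receptor", "ligand"),
      aa = c("A", "G"), seq_index = c(1L, 1L),
      x = c(0, lig_x), y = 0, z = 0))
  }
  expect_equal(nrow(extract_interface(mk(8.0))), 1)
  expect_equal(nrow(extract_interface(mk(8.001))), 0)
})

test_that("interface extraction matches the brute-force oracle and is monotone in cutoff", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      cx <- make_fixture_complex(sample(2:8, 1), sample(2:8, 1),
                                 contact_fraction = stats::runif(1),
                                 seed = sample.int(1e6, 1))
      got <- extract_interface(cx)
      want <- bf_interface(cx)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0) {
        expect_equal(sort(got$distance), sort(want$distance), tolerance = 1e-12)
      }
      inner <- extract_interface(cx, cutoff = 5)
      key <- function(df) paste(df$receptor_index, df$ligand_index)
      expect_true(all(key(inner) %in% key(got)))
    }
  })
})

test_that("fixture generator realises the requested contact fraction deterministically", {
  cx <- make_fixture_complex(3, 3, "AAA", "GGG", contact_fraction = 1, seed = 1)
  pairs <- extract_interface(cx)
  expect_true(all(pairs$receptor_aa == "A" & pairs$ligand_aa == "G"))

  cx0 <- make_fixture_complex(4, 4, contact_fraction = 0, seed = 2)
  expect_equal(nrow(extract_interface(cx0)), 0)

  for (frac in c(0.25, 0.5, 0.75)) {
    cx <- make_fixture_complex(8, 8, contact_fraction = frac, seed = 5)
    pairs <- extract_interface(cx)
    realised <- length(unique(pairs$ligand_index)) / 8
    expect_lte(abs(realised - frac) * 8, 1)
  }

  a <- make_fixture_complex(5, 5, contact_fraction = 0.6, seed = 9)
  b <- make_fixture_complex(5, 5, contact_fraction = 0.6, seed = 9)
  expect_identical(a$residues, b$residues)
})

test_that("complex construction enforces roles, ordering and the alphabet", {
  base <- tibble::tibble(chain_id = c("R", "L"), role = c("receptor", "ligand"),
                         aa = c("A", "G"), seq_index = c(1L, 1L),
                         x = 0, y = 0, z = 0)
  expect_silent(new_complex_structure("ok", base))
  bad_aa <- base; bad_aa$aa[1] <- "X"
  expect_error(new_complex_structure("x", bad_aa), "non-standard")
  only_rec <- base[1, ]
  expect_error(new_complex_structure("x", only_rec), "at least one")
  unordered <- dplyr::bind_rows(base, base[1, ] |> dplyr::mutate(seq_index = 1L))
  expect_error(new_complex_structure("x", unordered), "increasing")
})
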