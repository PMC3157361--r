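#' Construct a receptor-ligand complex structure
#'
#' Low-level constructor used by [parse_structure()] and
#' [make_fixture_complex()].  A complex holds one tidy residue table with a
#' receptor/ligand role per chain and C-alpha coordinates in Angstrom.
#'
#' @param id Structure identifier.
#' @param residues Tibble with columns `chain_id`, `role`
#'   (`"receptor"`/`"ligand"`), `aa` (single letters), `seq_index`
#'   (strictly increasing within chain), `x`, `y`, `z`.
#' @param complex_kind `"tcr_pmhc"` or `"antibody_antigen"`.
#' @return Object of class `complex_structure`.
#' @export
new_complex_structure <- function(id, residues, complex_kind = c("tcr_pmhc", "antibody_antigen")) {
  complex_kind <- match.arg(complex_kind)
  residues <- tibble::as_tibble(residues)
  stopifnot(all(c("chain_id", "role", "aa", "seq_index", "x", "y", "z") %in% names(residues)))
  if (!all(residues$role %in% c("receptor", "ligand"))) {
    stop("chain roles must be 'receptor' or 'ligand'", call. = FALSE)
  }
  if (!any(residues$role == "receptor") || !any(residues$role == "ligand")) {
    stop("complex needs at least one receptor and one ligand chain", call. = FALSE)
  }
  bad_aa <- setdiff(residues$aa, aa_alphabet())
  if (length(bad_aa) > 0) {
    stop("non-standard residue letters: ", paste(bad_aa, collapse = ","), call. = FALSE)
  }
  ok_order <- residues |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(ok = all(diff(.data$seq_index) > 0) || dplyr::n() == 1) |>
    dplyr::pull(.data$ok)
  if (!all(ok_order)) stop("seq_index must be strictly increasing within each chain", call. = FALSE)
  if (!all(is.finite(c(residues$x, residues$y, residues$z)))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  structure(list(id = id, residues = residues, complex_kind = complex_kind),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  n_by_role <- table(x$residues$role)
  cat(sprintf("<complex_structure '%s' (%s): %d receptor / %d ligand residues, %d chains>\n",
              x$id, x$complex_kind,
              n_by_role[["receptor"]], n_by_role[["ligand"]],
              length(unique(x$residues$chain_id))))
  invisible(x)
}

#' Parse a PDB-format complex into a structure object
#'
#' Reads ATOM/HETATM records (model 1) with bio3d, keeps one C-alpha per
#' residue (first alternate location wins), maps modified residues with an
#' unambiguous standard parent (e.g. MSE -> M) and skips any other
#' non-standard residue with a warning.  Chain roles are assigned
#' explicitly through `role_map`; for TCR-pMHC complexes the TCR chains are
#' the receptor side and MHC plus presented peptide together form the
#' composite ligand surface.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB text.
#' @param role_map Named character vector mapping chain id ->
#'   `"receptor"`/`"ligand"`.  Chains not named are ignored.
#' @param complex_kind See [new_complex_structure()].
#' @param id Identifier for the resulting structure.
#' @return A `complex_structure`.
#' @export
#' @examples
#' cx <- make_fixture_complex(3, 2, seed = 1)
#' cx2 <- parse_structure(write_pdb(cx), c(R = "receptor", L = "ligand"))
parse_structure <- function(pdb_text, role_map,
                            complex_kind = c("tcr_pmhc", "antibody_antigen"),
                            id = "structure") {
  complex_kind <- match.arg(complex_kind)
  if (!all(role_map %in% c("receptor", "ligand"))) {
    stop("role_map values must be 'receptor' or 'ligand'", call. = FALSE)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste(pdb_text, collapse = "\n"), tf)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)),
                  error = function(e) stop("not parseable as PDB: ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha atoms in file", call. = FALSE)
  missing_chain <- setdiff(names(role_map), unique(ca$chain))
  if (length(missing_chain) > 0) {
    stop("chains in role_map absent from file: ", paste(missing_chain, collapse = ","),
         call. = FALSE)
  }
  ca <- ca[ca$chain %in% names(role_map), , drop = FALSE]
  # first altloc wins
  key <- paste(ca$chain, ca$resno, ca$insert)
  ca <- ca[!duplicated(key), , drop = FALSE]
  aa <- unname(aa3to1[ca$resid])
  skipped <- unique(ca$resid[is.na(aa)])
  if (length(skipped) > 0) {
    warning("skipping non-standard residues without a 1:1 parent: ",
            paste(skipped, collapse = ","), call. = FALSE)
  }
  keep <- !is.na(aa)
  ca <- ca[keep, , drop = FALSE]
  aa <- aa[keep]
  for (ch in names(role_map)) {
    if (!any(ca$chain == ch)) {
      stop("chain ", ch, " has no standard residue with a C-alpha", call. = FALSE)
    }
  }
  # keep chains in file order; sort within chain by residue number + insert
  ord <- order(match(ca$chain, unique(ca$chain)), ca$resno, ca$insert, na.last = FALSE)
  ca <- ca[ord, , drop = FALSE]
  aa <- aa[ord]
  residues <- tibble::tibble(
    chain_id = ca$chain,
    role = unname(role_map[ca$chain]),
    aa = aa,
    seq_index = stats::ave(seq_along(aa), ca$chain, FUN = seq_along),
    x = ca$x, y = ca$y, z = ca$z
  )
  new_complex_structure(id, residues, complex_kind)
}

#' Write a complex structure as minimal PDB text
#'
#' @param cx A `complex_structure`.
#' @return Character scalar of PDB text (ATOM records, one CA per residue).
#' @export
write_pdb <- function(cx) {
  stopifnot(inherits(cx, "complex_structure"))
  r <- cx$residues
  aa1to3 <- stats::setNames(names(aa3to1)[1:20], aa3to1[1:20])
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(r)), aa1to3[r$aa], r$chain_id, r$seq_index, r$x, r$y, r$z
  )
  paste(c(lines, "END"), collapse = "\n")
}

#' Extract interface residue pairs
#'
#' Returns every receptor x ligand residue pair whose C-alpha atoms are
#' within `cutoff` Angstrom (inclusive) of each other.  Pairs within one
#' role are never reported; an empty result is legal geometry, not an
#' error.
#'
#' @param cx A `complex_structure`.
#' @param cutoff Distance cutoff in Angstrom; default 8.
#' @return Tibble with one row per pair: `receptor_chain`, `receptor_index`,
#'   `receptor_aa`, `ligand_chain`, `ligand_index`, `ligand_aa`, `distance`.
#' @export
#' @examples
#' cx <- make_fixture_complex(4, 4, contact_fraction = 1, seed = 1)
#' extract_interface(cx)
extract_interface <- function(cx, cutoff = 8.0) {
  stopifnot(inherits(cx, "complex_structure"), cutoff > 0)
  rec <- cx$residues[cx$residues$role == "receptor", ]
  lig <- cx$residues[cx$residues$role == "ligand", ]
  dx <- outer(rec$x, lig$x, "-")
  dy <- outer(rec$y, lig$y, "-")
  dz <- outer(rec$z, lig$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  tibble::tibble(
    receptor_chain = rec$chain_id[hit[, 1]],
    receptor_index = rec$seq_index[hit[, 1]],
    receptor_aa = rec$aa[hit[, 1]],
    ligand_chain = lig$chain_id[hit[, 2]],
    ligand_index = lig$seq_index[hit[, 2]],
    ligand_aa = lig$aa[hit[, 2]],
    distance = d[hit]
  ) |>
    dplyr::arrange(.data$receptor_index, .data$ligand_index)
}

resolve_seq <- function(spec, n, what) {
  if (is.character(spec) && length(spec) == 1) {
    letters <- assert_aa_string(spec, what)
    if (length(letters) != n) stop(what, " length must equal the residue count", call. = FALSE)
    return(letters)
  }
  comp <- if (is.null(spec)) uniform_composition() else surface_composition(spec)
  sample(aa_alphabet(), n, replace = TRUE, prob = comp)
}

#' Generate a synthetic receptor-ligand complex
#'
#' Builds a deterministic (per seed) two-chain complex whose interface
#' geometry is controlled exactly: receptor residues sit 10 Angstrom apart
#' along a line, the first `round(contact_fraction * n_ligand)` ligand
#' residues are each anchored ~5 Angstrom above one receptor residue (so
#' each is within the 8 Angstrom interface cutoff of exactly that
#' receptor), and the remaining ligand residues are displaced more than
#' 10 Angstrom from every receptor residue.
#'
#' @param n_receptor,n_ligand Residue counts (>= 1).
#' @param receptor_seq,ligand_seq Either an explicit sequence string of the
#'   right length, a composition to sample from, or `NULL` for uniform
#'   sampling.
#' @param contact_fraction Fraction of ligand residues in contact, in
#'   \[0, 1\]; realised exactly to within one residue.
#' @param seed Integer seed; fixed seed reproduces coordinates exactly.
#' @param complex_kind See [new_complex_structure()].
#' @param id Structure id.
#' @return A `complex_structure` (receptor chain "R", ligand chain "L").
#' @export
#' @examples
#' cx <- make_fixture_complex(3, 3, "AAA", "GGG", contact_fraction = 1, seed = 1)
#' nrow(extract_interface(cx))
make_fixture_complex <- function(n_receptor, n_ligand,
                                 receptor_seq = NULL, ligand_seq = NULL,
                                 contact_fraction = 1.0, seed = 1,
                                 complex_kind = c("tcr_pmhc", "antibody_antigen"),
                                 id = sprintf("fixture_%d", seed)) {
  complex_kind <- match.arg(complex_kind)
  if (n_receptor < 1 || n_ligand < 1) stop("residue counts must be >= 1", call. = FALSE)
  if (contact_fraction < 0 || contact_fraction > 1) {
    stop("contact_fraction must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    rec_aa <- resolve_seq(receptor_seq, n_receptor, "receptor_seq")
    lig_aa <- resolve_seq(ligand_seq, n_ligand, "ligand_seq")
    n_contact <- round(contact_fraction * n_ligand)
    rec <- tibble::tibble(
      chain_id = "R", role = "receptor", aa = rec_aa,
      seq_index = seq_len(n_receptor),
      x = 10 * (seq_len(n_receptor) - 1), y = 0, z = 0
    )
    anchor <- ((seq_len(n_ligand) - 1) %% n_receptor) + 1
    in_contact <- seq_len(n_ligand) <= n_contact
    lx <- 10 * (anchor - 1) + stats::runif(n_ligand, -1, 1)
    ly <- stats::runif(n_ligand, -1, 1)
    lz <- ifelse(in_contact, 5 + stats::runif(n_ligand, -0.5, 0.5), 60 + 10 * seq_len(n_ligand))
    lig <- tibble::tibble(
      chain_id = "L", role = "ligand", aa = lig_aa,
      seq_index = seq_len(n_ligand),
      x = lx, y = ly, z = lz
    )
    new_complex_structure(id, dplyr::bind_rows(rec, lig), complex_kind)
  })
}

#' Generate a campaign of synthetic complexes
#'
#' Produces a list of fixture complexes emulating a curated structure set.
#' Under `preset = "planted"` one residue pair is enriched at the
#' interface: with probability `planted_prob` a contacting receptor/ligand
#' residue pair is overwritten with `planted_pair`, giving the set a
#' recoverable immune-specific pair preference.  Under `preset = "null"`
#' ligand sequences are drawn i.i.d. from `comp`, so crystal and decoy
#' interfaces have identical composition and no potential signal exists.
#'
#' @param n Number of complexes.
#' @param preset `"planted"` or `"null"`.
#' @param seed Campaign seed.
#' @param n_receptor,n_ligand,contact_fraction Fixture geometry (the
#'   anchored 1:1 contact layout of [make_fixture_complex()]).
#' @param planted_pair Length-2 character: receptor then ligand residue.
#' @param planted_prob Per-contact probability of planting the pair.
#' @param comp Background ligand composition.
#' @param complex_kind Passed through to the fixtures.
#' @return List of `complex_structure` objects.
#' @export
fixture_campaign <- function(n, preset = c("planted", "null"), seed = 1,
                             n_receptor = 10, n_ligand = 10, contact_fraction = 0.8,
                             planted_pair = c("A", "G"), planted_prob = 0.5,
                             comp = surface_composition(),
                             complex_kind = "tcr_pmhc") {
  preset <- match.arg(preset)
  stopifnot(n >= 1, all(planted_pair %in% aa_alphabet()))
  n_contact <- round(contact_fraction * n_ligand)
  withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      rec <- sample(aa_alphabet(), n_receptor, replace = TRUE)
      lig <- sample(aa_alphabet(), n_ligand, replace = TRUE, prob = comp)
      if (preset == "planted" && n_contact > 0) {
        plant <- which(stats::runif(n_contact) < planted_prob)
        rec[plant] <- planted_pair[1]
        lig[plant] <- planted_pair[2]
      }
      make_fixture_complex(n_receptor, n_ligand,
                           receptor_seq = paste(rec, collapse = ""),
                           ligand_seq = paste(lig, collapse = ""),
                           contact_fraction = contact_fraction,
                           seed = sub_seeds[i], complex_kind = complex_kind,
                           id = sprintf("%s_%03d", preset, i))
    })
  })
}
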