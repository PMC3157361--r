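Package: ipvax
Title: Immune Receptor Interaction Potentials and Agent-Based Peptide
    Vaccination Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives empirical 20x20 residue-pair interaction potentials for
    immune receptor-ligand complexes (T-cell receptor against peptide-MHC,
    antibody against antigen, with a glycine-content split of the antibody
    set) from crystal-structure interfaces and sequence-randomised decoys,
    evaluates them with Mann-Whitney AUC campaigns against a general contact
    potential, and applies them inside a stochastic 3D lattice multi-agent
    simulation of peptide vaccination against a solid tumor.  Includes PSSM
    based MHC-binding prediction, thymic selection of random T-cell receptor
    repertoires, synthetic complex-structure fixture generators, and tidy
    tabular outputs with ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
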