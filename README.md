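# ipvax

Immune-specific residue-pair interaction potentials, and a multi-agent
lattice simulation of peptide vaccination against a solid tumor that uses
them to score every specific recognition event.

## The scientific problem

Peptide vaccination tries to direct cytotoxic T-cells against tumor
epitopes, but whether a given peptide, MHC genotype and schedule will
induce a response is hard to probe experimentally.  Two ingredients are
needed for a sequence-explicit *in silico* model:

1. **A recognition score.**  For a T-cell receptor (TCR) facing a
   peptide–MHC surface, or an antibody facing an antigen, `ipvax` derives
   an empirical 20×20 interaction potential from complex structures.
   Interface residue pairs are all (receptor, ligand) residues with
   Cα–Cα distance ≤ 8 Å.  Counting pairs in observed complexes
   (`C_crystal`) and in sequence-randomised decoys with protein-surface
   amino-acid composition (`C_random`), the potential is the normalised
   difference of mean per-structure counts,

   `M = (C_crystal / n_crystal − C_random / n_random)`, scaled so
   `max(M) = 1`.

   Positive entries mark residue pairs enriched in real immune
   interfaces.  Separate variants exist for TCR–pMHC (`IP_T`) and
   antibody–antigen complexes (`IP_B`), with the antibody set split at
   6.9 % interface glycine (the glycine frequency on protein surfaces)
   into `IP_B_high` / `IP_B_low`.  A receptor–ligand pair is scored as the
   mean potential value over the contacts of a structure-derived binary
   contact template; MHC alleles without a crystallised complex map to
   the template of highest global sequence identity.

2. **A systems model.**  A 3D lattice (one site ≈ a tissue micro-volume;
   8-hour steps) holds cancer cells, helper and cytotoxic T-cells,
   B-cells, macrophages and dendritic cells, plus antigen, antibody,
   IL-2 and a danger signal.  Injected peptides are taken up by APCs
   (unspecific for macrophages/DCs, potential-gated for B-cells),
   presented via position-specific scoring matrices (PSSMs), and
   recognised by T-cells with probabilities from the interaction
   potentials; recognition without the adjuvant danger signal anergises
   instead of activating.  Activated clones expand, kill cancer cells
   and presenting APCs, and drive the humoral arm.  T-cell repertoires
   are random sequences filtered through implicit thymic selection
   (positive and negative) before entering the lattice.

Derived potentials are validated with Mann-Whitney AUC campaigns: 90 %
training / 10 % validation splits, fresh decoys per subset, and a
head-to-head comparison against a bundled general hydropathy contact
table (synthetic stand-in for a generic knowledge-based potential).

## Worked example

```r
library(ipvax)

# derive a potential from a synthetic structure campaign and validate it
set <- fixture_campaign(200, "planted", seed = 1)
ev  <- evaluate_potential(set, seed = 2)
glance(ev)[, c("variant", "auc_train", "auc_validation", "p_validation")]
#> # A tibble: 1 × 4
#>   variant auc_train auc_validation p_validation
#>   <chr>       <dbl>          <dbl>        <dbl>
#> 1 IP_T        0.996          0.995 0.0000000850

# run a vaccination simulation (100 cancer cells, 5 µl, six injections
# 28 days apart, one simulated year of 8-hour steps)
cfg <- demo_config(seed = 1)
sim <- run_simulation(cfg)
glance(sim)
#> # A tibble: 1 × 6
#>   initial_cancer final_cancer eradicated_step peak_tc_active peak_th_active
#> 1            100           27              NA            147           1115

# percent tumor reduction relative to unlimited growth
untreated <- cfg; untreated$schedule <- integer(0)
reactiveness(sim, run_simulation(untreated))
#> [1] 84.57143
```

The evaluation says the derived potential separates observed from
decoy complexes nearly perfectly on held-out structures (validation AUC
0.995, p < 0.01).  The simulation run shrinks the tumor from 100 to 27
cells within the year — a successful but not eradicating treatment —
having expanded a peak of 147 active cytotoxic T-cells; against the
untreated trajectory (which doubles) that is 85 % reactiveness.

`autoplot(sim)` draws the population trajectories, `autoplot(ev)` the
crystal-vs-random score bars, and `bias_sweep()` /
`failure_profile()` reproduce the sensitivity and failure-mode analyses.
A command-line front end with `fixtures`, `derive-potential`, `score`,
`evaluate`, `mhc-predict`, `thymus`, `simulate`, `bias-sweep` and
`failure-profile` subcommands is installed at
`system.file("cli", "ipvax.R", package = "ipvax")`.

## Scope notes

The package derives potentials from any user-supplied curated structure
set but bundles no third-party data: synthetic fixture generators
(`make_fixture_complex()`, `fixture_campaign()`, `make_fixture_pssm()`)
stand in for curated PDB sets and externally trained MHC matrices, and
the bundled general contact table is a synthetic hydropathy construction,
not a published matrix.  The methods vignette
(`vignettes/interaction-potentials-and-simulation.Rmd`) documents the
model assumptions, parameter choices and limitations.
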