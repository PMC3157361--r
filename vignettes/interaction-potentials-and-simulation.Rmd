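---
title: "Immune interaction potentials and the vaccination lattice model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune interaction potentials and the vaccination lattice model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its two scientific components:
the derivation of empirical residue-pair interaction potentials for
immune receptor–ligand complexes, and the stochastic lattice model of
peptide vaccination that consumes them.  It documents the assumptions,
the parameters that matter, and the places where the design was
genuinely open and a choice had to be made.

## 1. The interaction potentials

### Model

Immune recognition — a T-cell receptor (TCR) engaging a peptide–MHC
surface, an antibody engaging an antigen — is scored with a
knowledge-based pair potential.  From a set of receptor–ligand complex
structures we count, over all structures, how often each ordered
amino-acid pair (receptor residue, ligand residue) occurs at the
interface.  Interface membership uses a single geometric rule: two
residues interact when their Cα atoms are at most 8 Å apart, boundary
inclusive, computed in double precision with no rounding.

Each observed complex is paired with sequence-randomised decoys: the
geometry and the receptor sequence are kept, and every ligand residue is
resampled independently from the amino-acid composition of general
protein surfaces.  The bundled composition fixes glycine at 6.9 % — its
surface frequency, which doubles as the antibody-set split point below —
and distributes the rest following broad surface trends (charged/polar
enriched, large hydrophobics depleted); it is user-overridable.

The potential is the difference of mean per-structure counts,

\[ M = \frac{C_\text{crystal}}{n_\text{crystal}} -
       \frac{C_\text{random}}{n_\text{random}}, \]

normalised by its maximum entry so that \(\max M = 1\) exactly
(bit-exact after the division).  Positive entries mark pairs enriched in
real immune interfaces, negative entries depleted ones.

Three derivation choices were open and are worth recording:

* **Count comparability.**  Dividing each count matrix by its number of
  contributing structures makes the subtraction unbiased when more than
  one decoy is generated per structure (`decoys_per_structure`, default
  1).  Plain unscaled subtraction would drift negative as decoys are
  added.
* **Plain subtraction.**  No logarithm or frequency transform precedes
  the subtraction; the difference of mean counts is used directly.
* **Normalisation denominator.**  The matrix is divided by its maximum
  (signed) entry, not the maximum absolute value; a derivation in which
  no pair is enriched (\(\max M \le 0\)) is reported as a degenerate-input
  error rather than silently flipped.

Variants: `IP_T` (TCR vs composite peptide–MHC surface; the MHC heavy
chain and the presented peptide together form the ligand side, the TCR
chains the receptor side) and `IP_B` for antibody–antigen complexes.
The antibody set is additionally split by the glycine fraction among
distinct ligand-side interface residues: strictly above 6.9 % goes to
the *high* set, at or below — ties deliberately to *low* — to the *low*
set.  Glycine-rich antigen interfaces permit sharper backbone turns and
appear to follow a slightly different recognition mode, which is why the
split reduces score variance.

### Scoring sequences without structures

Each template structure is reduced to a binary **contact matrix** (rows
= receptor positions, columns = ligand positions, 1 = interface pair).
A receptor/ligand sequence pair is then scored as the mean potential
value over the template's contacts; with \(\max M = 1\) the score never
exceeds 1.  Sequences longer than the template are scored over every
contiguous window and the best window wins — receptors in the simulator
have template-matched length, but antigens may be longer.  All-zero rows
or columns of the template cannot affect the score.  MHC alleles without
their own structure borrow the contact matrix of the template with the
highest global-alignment sequence identity (match 1, mismatch 0, unit
gap cost), ties broken lexically by template id.

**Score to probability.**  The simulator needs a probability per
recognition event, but the mapping from a mean-over-contacts score to a
probability is not dictated by the derivation.  Two strategies are
implemented: clamping to [0, 1] (the minimal monotone map, the default
of `score_to_probability()`), and a logistic
\( p = 1/(1+e^{-s(x - m)}) \) with slope \(s = 5\) per score unit and
midpoint \(m = 0.25\).  The simulation configuration defaults to the
logistic: the mean of ~18 potential entries for a random receptor
concentrates near zero, so clamping degenerates to "almost every
probability is 0" and no dynamics can start, whereas the logistic
spreads the same scores over a graded scale while preserving order.
The choice, slope and midpoint are configuration values, and the bias
sweep (below) quantifies how sensitive outcomes are to any monotone
rescaling of these probabilities.

### Validation campaigns

Structures are split 90 % / 10 % into training and validation (sizes by
round-half-away-from-zero, so 33 structures split 30/3); the potential
is derived on training crystals only, and both subsets are scored
together with freshly drawn decoys — validation decoys are never reused
from training, the conservative reading of an underspecified protocol.
Separation of crystal from decoy scores is summarised by the
Mann-Whitney AUC, computed as \(U/(n_1 n_2)\) with ties counted one
half; p-values use the tie-corrected normal approximation, or exact
enumeration of the permutation null when either group has fewer than 8
observations.  The report carries training, validation and pooled AUCs:
the training AUC is systematically optimistic (the potential is fitted
to its own noise), so claims rest on the validation rows.

As the curated structure sets behind the real potentials are not
bundled, the campaigns run on synthetic fixtures (section 3), and a
comparison against a *general* (non immune-specific) potential uses a
synthetic hydropathy-product contact table — the product of Kyte–
Doolittle indices, scaled to maximum 1 — which carries the dominant
hydrophobic signal of generic contact-energy tables but no
immune-specific pair preferences.

## 2. The vaccination lattice model

### State and step

A cubic lattice of \(L^3\) sites represents the simulated blood volume
(1600 sites per µl; the default 5 µl gives \(20^3\)).  Sites hold
integer cancer-cell counts and four molecule fields (antigen, antibody,
IL-2, danger signal).  Mobile agents — helper T (TH), cytotoxic T (TC),
B cells, macrophages (MA), dendritic cells (DC) — carry a type, an
activation state (resting / active / anergic / memory / plasma),
presentation flags, a division budget and, for TH/TC/B, a receptor
clone.  One step is 8 hours: a day is 3 steps, one simulated year 1095.
The default schedule injects at step 0 and five more times at 28-day
intervals (steps 0, 84, …, 420).

Each step applies, in fixed order: injection (antigen, plus danger
signal when adjuvanted, deposited uniformly); movement; phagocytosis
(MA/DC unspecific, MA additionally requiring local danger; B-cells
gated by their antibody-potential recognition probability);
MHC presentation with PSSM-derived probabilities; T-cell recognition of
presented peptide — activation if the site holds danger signal, anergy
(absorbing) otherwise; clonal expansion with memory formation; cytotoxic
killing of co-located cancer cells and presenting APCs; effector
contraction; the humoral arm (TH-stimulated presenting B-cells become
plasma plus memory, plasma secrete antibodies, antibodies clear
antigen); cancer division; molecule decay with a floor at zero.
Simultaneous-conflict resolution is by the order agents happen to be
drawn within the vectorised phase, itself a function of the seeded RNG
stream only: a configuration and seed fully determine the trajectory.

Recognition probabilities are precomputed per clone at initialisation
(the potential score of the clone's receptor against each injected
peptide on each allele's template, passed through the probability map)
— the step loop then draws Bernoulli events against cached values.  Two
global dials modify them: `bias` multiplies every potential-derived
probability (then clamps), and `recognition_override` replaces
recognition *and* presentation probabilities outright, giving the
zero-interaction (0) and saturation (1) controls.

### Parameters

Quantities stated by the study conditions: 100 initial cancer cells in
5 µl, 8-hour steps, one-year horizon, six injections 28 days apart, 50
self peptides per injected peptide, untreated tumor doubling in one
year.  The per-cell division probability follows from the last:
\((1+p)^{1095} = 2\), i.e. \(p = 2^{1/1095}-1 \approx 6.3\times10^{-4}\)
per step.

Everything else the model inherits from its cellular-automaton ancestry
without printed values lives in one overridable rates list
(`default_rates()`), chosen once as desk-scale calibrations: leukocyte
seeding densities scaled far below physiological counts (16/20/12/8/8
cells per µl for TH/TC/B/MA/DC) so a 5 µl volume holds hundreds of
agents; phagocytosis 0.9 per step; activated cells divide with
probability 0.3 per step (1.5× with local IL-2) against a budget of 6
divisions per activation event and die at 0.05 per step (contraction);
10 % of divisions yield memory cells, which re-recognise with a 2×
bonus; presenting APCs are killed by co-located active TCs with
probability 0.5 and otherwise lose their peptide-MHC complexes at 0.02
per step; plasma cells secrete 5 antibody units per step and die at
0.02 per step; molecules decay by factors 0.95/0.95/0.8/0.9 (antigen /
antibody / IL-2 / danger) per step with values below \(10^{-3}\) zeroed.
These are model constants in the sense of a simulation design, not
measurements.

Two structural choices deserve their own justification:

* **Tumor homing.**  Activated T-cells move one site toward the tumor
  centroid with probability 0.8 per step (otherwise a random step, as
  all other cells always do).  On a \(20^3\) lattice a pure random walk
  essentially never delivers a few hundred effectors onto a ~100-site
  tumor within a year; directed migration of activated lymphocytes into
  inflamed tissue is the biological license for this term.
* **Quiescence fast-forward.**  When no injection remains and every
  stimulus is gone (no antigen, danger, IL-2 or antibody anywhere; no
  ingested or presented peptide; no active or plasma cell), nothing but
  tumor growth can change the trajectory, and the engine advances the
  remaining steps with division draws only.  This is an exact shortcut
  at the level of reachable dynamics, not an approximation of them;
  similarly, a run stops early once the tumor is eradicated and carries
  terminal counts forward.

### Thymic selection

Before entering the lattice, each TCR clone is probed against every
(MHC allele, self peptide) pair; its self-reactivity is the maximum
interaction score.  Survival requires that maximum to reach
`positive_min` (positive selection: some MHC-self engagement) without
exceeding `negative_max` (negative selection: no strong
self-recognition).  No quantitative thresholds are given by the
underlying biology at this abstraction level, so they are explicit
calibration values: `calibrate_thresholds()` picks them from quantiles
of the score distribution of a reference random repertoire such that a
target fraction (default one half) survives, with 5 % removed from the
bottom.  B-cell repertoires undergo no thymic selection.  Selection is a
pure filter — survivors are a subsequence of the input — and the
package's tests check its monotonicity in both thresholds and in the
self-peptide set.

### Outputs and experiments

A run records, per step, every (type, state) population count, the
presenting-APC counts, molecule totals, and birth/death ledgers that
must balance the population differences exactly.  `classify_outcome()`
calls a run a success when the final cancer count is strictly below the
initial one; `reactiveness()` is the percent reduction of final tumor
burden against the matched untreated run (100 % = eradication), with
replicate summaries averaging the per-run ratios.  `failure_profile()`
tabulates, over replicate runs, which populations ever appeared in the
failing runs, separating experiments with under 50 % success (frequent
failures) from the rest.  `bias_sweep()` re-runs the simulation with
every potential-derived probability multiplied by a set of factors,
reporting relative final tumor size, mean steps until the tumor first
drops below its initial size, and success fraction per factor.

## 3. What the synthetic generators emulate — and what they do not

`make_fixture_complex()` builds two-chain complexes with exactly
controlled interfaces: receptor residues 10 Å apart on a line, each
contacting ligand residue anchored ~5 Å above one receptor residue
(inside the 8 Å rule for that residue and outside it for all others),
non-contact residues displaced beyond 10 Å.  The realised contact
fraction is exact to within one residue, and geometry is deterministic
per seed.  `fixture_campaign()` turns this into structure sets: the
*planted* preset overwrites each contact pair with a chosen residue pair
(default (A, G)) with probability 0.5, giving a single recoverable
enrichment signal; the *null* preset draws ligand sequences from the
decoy composition itself, so no signal exists by construction.
`make_fixture_pssm()` draws standard-normal position scores and sets the
binder threshold at a quantile (default 95 %) of simulated random-
peptide scores.

These fixtures emulate the *statistical* structure of curated sets —
enrichment against a background, train/validation generalisation, chance
behaviour under the null — but none of the *physical* structure of real
interfaces: no packing, no chain connectivity constraints, no correlated
pair preferences, no redundancy between homologous structures.  Passing
the package's campaigns therefore demonstrates that the derivation,
scoring and evaluation machinery is correct and statistically sound; it
does not certify any particular AUC on real crystallographic sets, which
depend on curation upstream of this package.

## 4. Numerical choices and degenerate inputs

* 8 Å boundary inclusive; distances in double precision.
* Split sizes round half away from zero (R's `round()` would round to
  even); the training side is clamped to leave at least one structure
  in each subset.
* Mann-Whitney: AUC exactly \(U/(n_1n_2)\) with ties at one half; exact
  permutation p below 8 per group, tie-corrected normal approximation
  otherwise, no continuity correction.
* Non-standard residues with a 1:1 standard parent (MSE, SEP, …) are
  mapped to it; others are skipped with a warning; a mapped chain with
  no usable Cα is an error.  First alternate location wins; insertion
  codes order within a chain.
* An empty interface is legal geometry for extraction (empty result),
  an error for glycine fraction, contact-matrix construction and
  complex scoring (the quantity is undefined).
* Derivation with \(\max M \le 0\) errors; normalisation makes the
  maximum exactly 1 by construction.
* Molecule fields are clamped at zero after every clearance and decay;
  values under \(10^{-3}\) are zeroed so exponential decay terminates.
* All stochastic entry points take explicit seeds; internal sub-seeds
  are drawn below \(2^{31}\).

## 5. Problem sizes used by the tests and the acceptance script

The test suite validates the potential machinery on 100-plus randomized
fixtures against brute-force oracles, recovery and generalisation on
200-structure planted and null campaigns, and the simulator on the
standard configuration (\(20^3\) lattice, 100 cancer cells, 1095 steps)
with 100 replicates per stochastic claim (untreated growth, saturation,
zero-recognition, adjuvant-off, bias sweep at factors 0, 1, 3).  The
acceptance script recomputes the same quantities with 25 replicates per
simulation campaign.  These sizes are the package's chosen desk-scale
study conditions; the generators and engine accept larger ones
unchanged.

## 6. Known limitations

* Only IL-2 and a scalar danger signal are modelled — no wider cytokine
  panel, no regulatory T-cells, no tumor mutation or antigen-expression
  escape, no metastasis.  These are outside the model's scope.
* Class II presentation uses a fixed 9-mer core; variable-length core
  alignment is not modelled.
* The antibody arm uses a single contact template, treating injected
  peptides as their own B-cell epitopes (reasonable for short peptides
  without stable tertiary structure, wrong for folded antigens).
* Agent kinetics are desk-scale calibrations; absolute cell counts and
  time-to-eradication should be read qualitatively, not as predictions.
* The potentials are only as good as the structure set they are derived
  from; the package ships no curated set and makes no claim about
  accuracy on real complexes.
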