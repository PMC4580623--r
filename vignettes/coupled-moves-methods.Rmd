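---
title: "Coupled-moves design: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-moves design: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledmoves)
```

This vignette is the package's own account of its science: the sampling
model and its assumptions, the parameters that matter, the reference energy
function and its deliberate simplifications, the numerical choices, and the
limits of what the synthetic test systems can show. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The sampling model

The state of a simulation is a *pose*: one protein chain set (backbone and
side-chain coordinates, amino-acid identities, chi angles) plus an optional
ligand (a fixed atom topology with a set of discrete conformers and a
rigid-body frame). A *design task* lists which positions may mutate
(design) and which may only change conformation (repack).

Each Monte Carlo move is a **coupled proposal**, accepted or rejected as
one unit:

* **Protein move** (probability 1 − `p_ligand`, default 0.9). A pivot is
  drawn uniformly from the design and repack positions. In the
  flexible-backbone variant the backbone is perturbed by a three-residue
  backrub: the segment strictly between the flanking alpha-carbons — C and
  O of residue i−1, all of residue i, N (and its amide hydrogen) of residue
  i+1 — rotates about the Cα(i−1)→Cα(i+1) axis by θ ~ N(0, σ²) with
  σ = 4.57° by default, the width of backrub-like motions observed between
  alternate conformations in high-resolution crystal structures. Two
  follow-up rotations of the flanking peptide groups about their own Cα–Cα
  axes minimize the summed squared displacement of the C=O and N–H group
  atoms (independent 1-D golden-section minimizations via
  `stats::optimize`, tolerance 1e-6°). Both rotations are exact rigid
  motions, so the flanking alpha-carbons are exact fixed points and every
  bond length is preserved to machine precision — properties the test suite
  asserts over a thousand random moves. On the perturbed backbone the
  rotamer set at the pivot is regenerated and scored, and a side chain is
  selected in two Boltzmann stages: one rotamer per amino acid, then one
  amino acid among the per-amino-acid winners, with
  P(E_i) = exp(−E_i/kT)/Σ_j exp(−E_j/kT) and E_i the candidate energy
  relative to the current side chain. Repack-only positions skip the second
  stage.
* **Ligand move** (probability `p_ligand`, default 0.1). A rigid-body
  rotation about a random axis through the ligand centroid
  (angle ~ N(0, 1°²)) plus an isotropic translation whose *total*
  displacement has standard deviation 0.1 Å, followed by Boltzmann
  selection of a conformer on the new frame. Conformers carry a uniform
  prior.

The Metropolis criterion at constant kT = 0.6 (the same temperature used in
the selection stages) accepts the coupled move. Every accepted sequence
change over the design positions is recorded; the output of a simulation is
the ordered list of unique sequences, the per-move ledger (a tibble), and
the lowest-energy pose per unique sequence. Default study conditions are
1000 moves per simulation and 20 independent simulations pooled with
redundancy filtering, simulation s seeded with `seed + s`.

The `sc_selection = "uniform"` variant replaces both selection stages (and
conformer selection) by uniform draws; `backbone = "fixed"` skips the
backrub. These reproduce the protocol's ablation axes. The baseline
comparator, `run_fixed_backbone_design()`, is a standard packer: uniform
(position, rotamer) proposals under a geometrically cooled Metropolis
schedule (8 stages, kT 100 → 0.3 by default; the schedule is a package
choice, exposed in `anneal_schedule()`), backbone and ligand frozen.

### What the chain samples

Boltzmann-*selected* proposals followed by plain Metropolis acceptance on
the energy change double-count the energy bias. On a two-state landscape
with energies (0, 0.6·ln 3) at kT 0.6 the Boltzmann distribution is
(0.75, 0.25), but detailed balance for the protocol's chain gives
occupancy (0.9, 0.1): from the ground state the excited state is proposed
with probability 0.25 and accepted with probability 1/3, while the reverse
move is proposed with probability 0.75 and always accepted. The protocol is
a design optimizer, not a canonical sampler, and the package treats this
property honestly: `run_landscape()` defaults to the Metropolis–Hastings
acceptance corrected for the proposal distribution (which always accepts
when the selection energies equal the state energies, so the chain samples
the Boltzmann distribution exactly and serves as the stationarity oracle),
while `acceptance = "metropolis"` reproduces the protocol's biased chain —
both behaviours are asserted by tests.

## The reference energy function

The sampler is energy-function-agnostic: it needs only the decomposition
contract — per-position one-body terms, unordered-pair two-body terms, and
a protein–ligand component scaled linearly by `w_lig` (default 1; the
benchmark settings elsewhere are 2 and 3). `score_pose()` returns that
decomposition and the identity
`total = Σ one_body + Σ two_body + w_lig · protein_ligand` holds to 1e-8.

The packaged reference implementation sums, over heavy-atom pairs more than
three bonds apart and within a 10 Å cutoff:

* a 12-6 Lennard-Jones term with σ = r_i + r_j and ε = √(ε_i ε_j) from a
  small per-element table, split Weeks–Chandler–Andersen style into
  attractive and repulsive components. The repulsive branch is linearized
  below 0.6·σ so overlapping atoms stay finite ("soft" repulsion). The
  repulsive component alone is the **clash energy**: repack neighbours are
  selected where any rotamer of a design position has pairwise repulsion
  above 5 energy units against a residue's current side chain, the package's
  reading of the clash rule (repulsion is the only term that grows without
  bound on overlap);
* a directional hydrogen bond between a polar hydrogen and an acceptor
  heavy atom: donor–acceptor distance window 1.5–3.3 Å with a
  squared-cosine ramp peaking at 2.8 Å, times a squared-cosine falloff in
  the D–H···A angle (zero below 90°), well depth configurable
  (`hb_depth`, default 2). An ideal linear bond at optimum distance scores
  exactly −`hb_depth`. Polar hydrogens (backbone amides, hydroxyls, side
  chain N–H donors) are placed deterministically from ideal geometry and
  carry no Lennard-Jones term;
* a rotamer self-energy −ln(prob) from the library probability; and
* per-amino-acid reference energies (a vector of 20 constants, default 0).

Deliberate simplifications, stated plainly: no solvation (so hydrophobic
burial is rewarded only through dispersion contacts), no electrostatics
beyond the hydrogen-bond term, cysteine and histidine do not donate
hydrogen bonds (histidine nitrogens accept), ligand atoms accept (O, N) but
never donate, and intra-side-chain hydrogen bonds are not scored. Energies
are in arbitrary units calibrated only in the sense that kT = 0.6 gives
reasonable acceptance behaviour; no claim is made that they approximate any
published all-atom force field, and headline accuracies reported for the
protocol under such force fields are out of reach of this stand-in by
construction.

Incremental scoring (`delta_energy()`, and the samplers' internal fast
path) re-evaluates only the terms a move touches and agrees with a full
rescore to 1e-6; a property test drives 100 random mixed moves through both
paths. One subtlety: mutating to or from proline changes the backbone
amide-hydrogen set, which the batched candidate shortcut cannot see, so
such moves fall back to an exact local rescore.

## Rotamers

The default library is **synthetic**: a pure function of (amino acid,
phi bin, psi bin) on a 10° grid that returns canonical chi-well rotamers
(sp3 chi1 wells at −60/180/60 favouring gauche−; outer sp3 chis favouring
trans; aromatic chi2 at ±90; carboxyl/amide terminal chis at 0/±90) whose
weights vary smoothly and deterministically with the bin, truncated at 95%
cumulative probability. It has the structural contract the sampler needs —
purity, backbone dependence, normalized probabilities — but its
probabilities are not survey statistics, because the standard
backbone-dependent library is not redistributable. Ser/Thr/Tyr rotamers are
expanded over three hydroxyl proton positions (±60/180) so the
hydrogen-bond term can be scored; no further sub-rotamer expansion is done.
Table-backed libraries load through `read_rotamer_library()` (documented
TSV: `AA PHI_BIN PSI_BIN PROB CHI1..CHI4`; a small example ships in
`inst/extdata/`, synthetic numbers) or `read_dunbrack_library()` for the
standard text format.

The current side-chain conformation is always appended to every candidate
set, so the null move exists and the chain is aperiodic; the source does
not state this convention and it is a package decision. The current
rotamer keeps the probability it was built with, so the −ln(prob)
self-energy is a pure function of the rotamer and incremental totals stay
exact; consequently the per-amino-acid probability sum can slightly exceed
1 once the current rotamer is appended (library rows alone sum to ≤ 1).

Backbone dihedrals at chain termini are not defined; `get_rotamers()`
substitutes the canonical helical values (−57, −47), an arbitrary but fixed
fallback. Terminal residues also cannot pivot a backrub, so protein moves
at chain ends are side-chain-only. Proline is modelled with a single fixed
ring rotamer; its ring-closure bond to the backbone nitrogen is
approximate (ideal internal coordinates do not close the ring exactly),
which is acceptable because proline is never the engineered target in any
fixture.

## Benchmark metrics

**Percent enrichment.** PE(WT→MUT) = %non-native − %native, where the
percent occurrence of a mutation is the fraction of *unique* pooled
sequences carrying that amino acid at that position (the protocol pools
redundancy-filtered sequences; whether occurrence should instead be counted
with multiplicity is not recoverable from the source, and unique sequences
are the consistent choice). Candidates are every (position, amino acid)
observed in either set and differing from the start residue, ranked by
descending PE with ties broken by (position, amino acid) order for
determinism; percentile = 100·(N − rank + 1)/N over the N ranked
candidates, which anchors rank 1 at the 100th percentile. A prediction is
correct iff PE > 0.

**Profile similarity** is 1 − D_JS(p, q) with equal mixture weights and
base-2 logarithms, so it spans [0, 1]; **sequence entropy** uses base-20
logarithms so the uniform distribution scores 1. Alignment columns
containing gaps are dropped with a warning (natural alignments are expected
to be gap-filtered upstream). Entropy tertiles sort positions by natural
entropy; when the count is not divisible by three the extra positions go to
the lower-entropy groups, and ties resolve by stable sort order.
Significance: two-sided Fisher's exact test on correct/incorrect counts and
a paired two-tailed t-test on per-position similarity vectors (the paired
design leaves no room for an unequal-variance correction; degenerate inputs
return p = 1 with a warning).

## Synthetic test systems

`make_helix_pose()` builds ideal-geometry alpha-helices (φ = −57, ψ = −47,
ω = 180, ideal bond lengths and angles), with side chains from the library's
top rotamer followed by a deterministic greedy repack so fixtures start
clash-free. Idealized geometry keeps the geometric invariants exact to
tight tolerances; no experimental noise, B-factors or crystallographic
disorder are emulated.

`make_toy_complex()` places a probe ligand so that a known pocket mutation
is favoured, and **verifies its own ground truth at build time** by
brute-force enumeration of the best energy of every candidate amino acid,
failing loudly if the intended gap (default 5 kT = 3 energy units) is not
achieved. Three shapes: a single-atom apolar probe at the Lennard-Jones
optimum of the wild-type side-chain tip; a two-atom dumbbell scanned inward
until the wild type clashes while the target stays comfortable (the
documented gap is target-vs-wild-type — with sterics alone glycine and
alanine also relieve any clash, so a steric fixture cannot make one small
amino acid the unique winner); and a hydrogen-bond acceptor probe placed on
the donor axis of the target hydroxyl rotamer, which makes the target the
*global* winner by ≥ 5 kT. The hydrogen-bond fixtures use a deepened well
(`hb_depth = 6`) because the three-way proton-chi expansion costs the
hydroxyl rotamer about −ln(p/3) ≈ 1.8 units of self-energy that the bond
must out-compete; this is a fixture construction constant, set by the gap
requirement, not a tuned value. The specificity pair
(`make_specificity_pair()`) restricts the pocket candidate set to exclude
threonine and tyrosine — which share the hydroxyl donor and would tie the
target — and keeps hydroxyl-free amino acids at the two neutral diversity
positions, so the engineered bond is uniquely available to the target. This
is a controlled-fixture choice: it demonstrates the benchmark logic, not
design accuracy on real systems.

Passing these tests shows the machinery is correct — move geometry exact,
selection laws analytic, bookkeeping consistent, benchmark arithmetic right
— on small, engineered, idealized systems. It does not show that designs on
real protein–ligand complexes are accurate: that depends on the energy
function, the rotamer statistics, and starting-structure quality, all of
which the synthetic systems idealize away.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by choice:
nine-to-twenty-residue helices, one-to-three design positions, 150–600
moves per simulation, and 20 seeds or replicates per statistical claim —
large enough for the analytic tolerances (3σ binomial bounds,
family-corrected when many cells are checked jointly) and small enough to
run in minutes. The protocol defaults (1000 moves, 20 simulations) remain
the configured study conditions.

Numerical conventions: degrees at every interface, radians only inside
geometry kernels; Å for lengths; 1-based residue numbering keyed by
(chain, seqpos), never flat indices; softmax with max-shift so huge energy
gaps never overflow; backrub angles are sampled unclamped and |θ| ≥ 90°
proposals are rejected as pathological; Kabsch superposition with an SVD
determinant correction and an explicit collinearity error; and fixed seeds
make every trace bit-reproducible (simulation s of an ensemble uses
`seed + s`).

## Known limitations

Beyond the energy-function simplifications above: no insertions or
deletions and no loop remodelling (backbone changes are local backrubs
only); no explicit water; single-chain protein plus one ligand (no
cofactor/substrate pairs); no mmCIF or multi-model input; ligand conformers
must be supplied (no on-the-fly torsion sampling); and no continuous chi
minimization of rotamers.
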