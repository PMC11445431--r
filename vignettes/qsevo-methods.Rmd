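---
title: "Methods: quaternary-structure evolution from structures and phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quaternary-structure evolution from structures and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsevo)
```

qsevo analyses how the cellular environment shapes the quaternary structure
(QS) of enzymes: whether a protein works as a monomer or as a homomer, how
large and conserved its self-interaction interfaces are, and how QS states
evolve along phylogenies. The package implements the full computational chain
— surface areas from structures, interface calling, interface-homology
grouping, ancestral-state reconstruction, ratchet statistics, and annotation
scores — together with synthetic-data generators that give every stage a
known ground truth.

## Solvent accessibility and interface calling

Solvent-accessible surface area (SASA) is computed with the Shrake–Rupley
algorithm: quadrature points are placed on each atom's sphere expanded by the
probe radius, and a point is accessible when it lies outside every
neighbouring expanded sphere. Two numerical choices matter:

* **Point set.** Points come from a golden-section spiral, not random
  sampling, so areas are bit-reproducible. The default `n_points = 960`
  brings the single-sphere quadrature error well below 1%, and doubling the
  count changes areas by less than 1%.
* **Radii.** A NACCESS/Chothia-style element table (C 1.87, N 1.65, O 1.40,
  S 1.85 Å) with a 1.4 Å water probe. Both are configurable; results at
  these defaults are close enough to common SASA tools for threshold-based
  region calling. Waters and hetero atoms are excluded by default, the
  highest-occupancy alternate conformer is kept, and the first model of
  multi-model files is used.

A complex is partitioned into its chains with coordinates frozen, and SASA is
computed for the assembly and for each isolated subunit. Residue regions then
follow two thresholds (both strict inequalities, both configurable):

* **interface** — SASA drops by more than `delta_frac` (default 10%) of the
  subunit SASA on assembly, and the subunit relative solvent accessibility
  (RSA, Miller reference areas) exceeds `rsa_min` (default 20%);
* **surface** — not interface, RSA above 20%;
* **core** — everything else. Residues with zero subunit SASA cannot satisfy
  the relative-drop rule and fall to core.

Per-complex interface area is `(sum of subunit SASAs − complex SASA) /
n_subunits`, computed from totals exactly as defined, independently of the
per-residue called set; relative buried surface divides the same difference
by the subunit SASA sum. Hydrophobicity of a region is its fraction of
C, F, I, L, M, V, W. Where a per-chain residue set is needed (hydrophobicity,
conservation, overlap), the first subunit is used; this is configurable, and
for near-symmetric homomers the choice is immaterial.

## Structural correspondence and interface overlap

Orthogroup members are homologous, so residue correspondences between two
subunits are obtained from a global sequence alignment (BLOSUM62, gap open
11, extend 1) and refined structurally: alternating least-squares (Kabsch)
superposition and rejection of pairs beyond 5 Å until the retained set is
stable. The TM-score over all corresponded pairs uses the standard
`d0 = 1.24 (L − 15)^{1/3} − 1.8` (floored at 0.5 Å) and is normalized by the
smaller chain, which makes it symmetric. Exact parity with fragment-based
structural aligners is not claimed; an import path for externally produced
correspondences (`pairs` argument / `--pairs-in`) exists for that purpose.

Interface overlap between two complexes is the number of corresponded residue
pairs that are interface on both sides, divided by the smaller interface.
Because of the min-normalization, "at least half of the smaller interface is
shared" is a single symmetric edge rule; interfaces are grouped by the
connected components of that graph at threshold 0.5. Undefined overlaps
(empty interfaces) are excluded from averages rather than imputed as zero.

## Quaternary-structure states

States are assigned in two modes: binary (monomer vs homomer) and
multi-state, where the state identity is the pair (subunit count,
interface-homology group) — complexes with equal subunit counts but
non-homologous interfaces are distinct states, and all monomers share one
state. "Similar number of subunits" is read strictly as equality. Homomers
whose per-subunit interface area falls below 1000 Å² are treated as probable
QS assignment errors and demoted to monomers (`qs_error_filter`);
the threshold is configurable.

## Ancestral reconstruction

Discrete-trait evolution is modelled with the equal-rates (ER) Markov model.
The pruning likelihood uses the closed-form ER transition probabilities
(`P_stay(t) = 1/k + (1 − 1/k) e^{−kqt}`), a flat root prior `1/k`, per-node
rescaling against underflow, and all-ones partials for missing tips. The
single rate is fitted by bracketing the optimum on a 40-point log-grid
followed by golden-section refinement (tolerance 1e-8); the grid step matters
because the ER likelihood flattens at large rates and a naive line search can
settle on that plateau. Marginal ancestral probabilities come from the
standard two-pass (downward partials × upward messages) algorithm; both the
likelihood and the marginals are tested against exhaustive enumeration over
all internal labelings on all 3–5-leaf topologies.

Maximum parsimony uses Hartigan's generalization of Fitch (exact on
multifurcations, identical to Fitch on binary trees) with ACCTRAN-style
resolution: ambiguity prefers the parent's assigned state, then the lowest
state index, so reconstructions are deterministic. Scores are tested against
the exhaustive minimum on all 945 rooted 6-leaf topologies.

Downstream counting needs a single state per node. An internal node is
*determined* when its maximum marginal probability exceeds 0.5 (mirroring,
at internal nodes, the convention that a tree is kept only when its root
state reaches 51%); ties and flatter nodes are undetermined and their
incident parent–child pairs are excluded from both numerator and denominator
of the change statistics. Leaves with annotations are always determined.
Trees are midpoint-rooted when no rooted topology is supplied; only a rooted
topology with branch lengths is needed downstream, and externally rooted
trees are accepted as-is.

## Ratchet statistics

`change_frequency` is the fraction of determined parent–child pairs whose
states differ. `gain_loss_counts` compares subunit counts: child larger →
gain, smaller → loss; homology-group switches at equal counts count as
changes but neither gains nor losses, and a multi-rung jump on one edge is a
single event (node pairs are counted, not subunits). Trees fixed in a single
state are retained with change frequency 0. Per-orthogroup reports add mean
root-to-leaf distance, mean pairwise leaf distance, the extracellular leaf
fraction, and the modal QS among extracellular leaves (ties → missing),
with location summaries requiring at least five located leaves.

## Annotation scores

The conservation differential is the difference of mean normalised
conservation scores between interface and surface (interface − surface,
ConSurf convention: lower = more conserved; the sign convention is
configurable). Significance uses a two-sided Wilcoxon rank-sum test at
alpha 0.05 — the test is not dictated by the upstream definitions, and the
rank-sum choice matches the nonparametric comparisons used throughout this
kind of analysis; the flag additionally requires the conserved direction, so
under a true null it fires at about alpha/2. Synthesis cost per region is
the mean of per-residue costs in high-energy phosphate bonds
(Akashi–Gojobori E. coli values; the shipped table is the integer-valued
variant anchored at Ala/Gly/Ser = 11 and Trp = 74, asserted at load time).
Abundances (ppm) are scaled by subunit count to approximate particle
concentrations; homomers with unknown counts are assumed dimers when the
fallback is enabled.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of an explicit seed.

* **Toy complexes** (`gen_cn_complex`) are compact self-avoiding pseudo-atom
  chains (one 1.9 Å sphere per residue) replicated by a Cn rotation and slid
  toward the axis until adjacent chains touch (minimum inter-chain bead
  distance 4.0–4.6 Å, found by bisection). The designed buried set is every
  bead within `2r + probe` = 5.2 Å of a neighbouring chain — below that
  separation the probe centre cannot pass between the spheres, so assembly
  must bury measurable area. Because the beads have no side chains, RSA for
  toys uses the isolated-bead sphere area (`toy_reference_areas()`), not
  Miller values. Toys exercise geometry and thresholds; they do not mimic
  real folds, secondary structure, packing densities or sequence evolution,
  so recovery rates on toys say nothing about interface calling in
  low-resolution or NMR structures.
* **Trees** (`gen_birth_tree`) are pure-birth (Yule) trees at unit birth
  rate, started from two lineages, with pendant branches extended by a final
  waiting time; expected height is `sum_{k=2..n} 1/k`, which the tests check
  in closed form.
* **Trait histories** (`sim_trait_history`) are exact stochastic simulations
  of a continuous-time Markov chain along each branch with a full event log;
  replaying the log must reproduce every node state. The ratchet study uses
  a subunit-count ladder {1, 2, 4} with gain rate 0.3 and loss rate 0.1 per
  unit branch length from a monomer root (a 3:1 bias, a few events per
  20-leaf tree), and 0.2/0.2 from a dimer root for the symmetric control.
  At these rates roughly 40% of root-to-tip paths change state, which is
  deliberately on the saturated side: it makes the *true* histories show
  more gains than losses in essentially every tree, while reconstruction
  (either ML-marginal with the 0.5 determination rule or ACCTRAN) recovers
  the per-tree direction in about 75–85% of trees. The shortfall is a
  property of ancestral reconstruction itself — trees without any gain
  event, equally parsimonious gain+loss reconstructions of paraphyletic
  derived clades, and root-polarity inversions when an early event flips a
  large clade — and the last two failure modes do not vanish at any rate
  scale at this tree size; the aggregate direction (mean gains vs mean
  losses) is recovered robustly.
* **Conservation scores and abundances** are Gaussian (interface shifted by
  a configurable amount) and lognormal (homomers shifted on the log scale,
  subunit counts from a configurable distribution). Construction makes
  subunit scaling remove a `log 2` dimer shift exactly, reproducing the
  qualitative pattern that homomer abundances exceed monomer abundances in
  enzymes but particle concentrations do not.

## Dataset filtering and the pipeline

`filter_dataset` keeps records with resolution strictly better than 3 Å
("better than" is read as strict), UniProt coverage ≥ 80% and mature length
≥ 100 residues (both "minimum of", hence inclusive), and a monomer/homomer
label; drops are tallied by the first failing rule. `run_pipeline` chains
filter → interface profiles → overlap/homology states → ER reconstruction →
per-orthogroup report, writing one TSV per stage with a parameter-echoing
log; completed stages are reused on rerun unless forced, and rerunning with
the same configuration reproduces the outputs byte-for-byte.

## Problem sizes and limitations

The test-suite and reproduction scripts use 100 seeded toy dimers of 40
residues for interface recovery, 200 trees of 20 leaves per ratchet arm,
1000 replicates for the null calibration of the conservation flag and
200 for the abundance comparisons at 300 proteins per group — sizes at which
every stochastic check is stable across seeds while the whole suite stays
interactive.

Known limitations: no crystallographic symmetry expansion (deposited
coordinates are taken as the biological assembly); ΔSASA-only interface
definition (no distance-cutoff or bond-typed interfaces); one residue set
per complex (multiple distinct interface patches are not split); ER-only
trait model (no asymmetric-rates ML, by design); midpoint rooting as the
default stand-in for deviation-based rooting; and sequence-guided rather
than sequence-independent structural correspondence, which assumes the
compared subunits are homologous.
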