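---
title: "Virtual coformer screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual coformer screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coformr)
```

## The screening problem

Cocrystals — stoichiometric crystalline solids of an active pharmaceutical
ingredient (API) and a benign partner molecule (coformer) — can rescue the
dissolution behaviour of poorly soluble drugs without altering covalent
structure. The bottleneck is coformer selection: experimental screens over
hundreds of GRAS-listed candidates are expensive, and empirical selection
rules are weak. coformr implements a two-stage computational funnel that
reduces a coformer library to a short, ranked candidate list:

1. **Complementarity screening.** Statistical analysis of known cocrystals
   shows that co-crystallising molecules tend to have similar polarity and
   similar shape. Each coformer is compared with each API conformation on
   five descriptors — dipole moment, fractional polar volume (FPV), the
   M/L and S/L ratios of the minimum rectangular box enclosing the van der
   Waals volume, and the short box axis S — and passes a conformation when
   every absolute difference is within its cutoff. Coformers passing more
   than half of the API conformations advance.
2. **Hydrogen-bond propensity (HBP).** Complementary pairs can still prefer
   bonding to their own kind. A logistic model over donor/acceptor site
   descriptors assigns each possible donor–acceptor pairing a propensity;
   the *multi-component score* (best API↔coformer propensity minus best
   like–like propensity) flags heterosynthon-forming pairs. Positive scores
   favour cocrystallisation, negative scores flag homosynthon formers.

The final ranking sorts by conformations passed, then multi-component
score, then polarity closeness ahead of geometric closeness.

## Why an ensemble of API conformations

A coformer compatible with only one API conformation requires that geometry
to survive processing, which is rarely realistic. The API is therefore
embedded as an ensemble (`generate_conformers()`, default 9 conformations —
the source protocol reports both nine and ten; nine is the default and the
size is a config parameter). Embedding uses seeded ETKDG distance geometry
with MMFF94 minimisation through RDKit; candidates are over-sampled and
pruned at 0.5 Å heavy-atom RMSD so the ensemble contains genuinely distinct
shapes. Everything is bit-reproducible for a fixed seed, which the package
treats as a hard contract: two screening runs with the same config and seed
produce byte-identical reports.

Conformations are sanity-checked by `validate_geometry()` against a static
table of allowed bond-length/angle windows (generous mean ± 4σ style ranges
per feature class). This emulates the role of a crystallographic geometry
library without database access; the table is deliberately user-replaceable
(CSV) because a static window check is weaker than distributions derived
from curated crystal structures. Features with no table entry are reported
as *uncovered* rather than silently passing.

## Descriptors

* **Van der Waals volume** is integrated on a voxel grid (default 0.2 Å;
  finer grids converge at ~2 % for drug-size molecules, and the analytic
  single-sphere case is reproduced within 2 % at 0.1 Å). The **polar
  volume** assigns each covered voxel to its nearest covering sphere (ties
  to the lower atom index); FPV is the polar fraction. A per-atom-count FPV
  variant is available (`fpv_mode = "atom_count"`) because the field uses
  both conventions; the volumetric definition is the default, matching the
  box-model construction the screen descends from.
* **Box axes**: the minimum-volume rectangular box enclosing all vdW
  spheres, found by a coarse 10° rotation-grid search over a covering
  orientation domain followed by Nelder–Mead refinement of the Euler
  angles, with the principal-axes orientation as an extra candidate (so the
  result never exceeds the PCA-aligned box). Against an exhaustive 2°
  rotation-grid search the refined volume agrees within 1 % on random
  clusters. Axes are reported sorted S ≤ M ≤ L.
* **Dipole moment**: |Σ qᵢrᵢ| over Gasteiger partial charges, converted at
  1 e·Å = 4.80321 D. Charges are renormalised to the exact formal net
  charge so neutral molecules have an exactly origin-independent dipole;
  charged species trigger a warning instead. Gasteiger charges are a
  different model from the charge models behind published reference
  dipoles, so published per-molecule dipole values are carried as fixture
  metadata, never recomputed.

## Cutoffs and boundary conventions

The polarity cutoffs default to the published values: dipole delta within
**5.94 D** (inclusive) and FPV delta strictly below **0.294**. The
inclusive/strict asymmetry mirrors the wording of the source protocol
("within" vs "less than"). The geometric cutoffs (M/L delta, S/L delta,
S-axis delta) are referenced to a table that is not reproduced in the
available text; rather than fabricate defaults, they are **config-mandatory**
(`cutoff_set()` errors without them) and a shipped example config
(`inst/extdata/cutoffs.yaml`) carries round illustrative values (0.25,
0.25, 2.5 Å).

**Optimal deviancy** ranks coformers that passed: it is 100 × the mean
(over passed conformations) of the mean (over the five descriptors) of
delta/cutoff. 0 % means descriptors identical to the API; 100 % means every
delta sits at its limit; lower is more complementary. The source describes
this metric only qualitatively (an "arbitrary ranking system"); the mean
fractional tolerance use is the simplest formula with the stated direction,
and its known blind spot — one descriptor nearly at its limit hidden by
others near zero — is inherited deliberately rather than redesigned.

## The hydrogen-bond propensity model

Sites are enumerated from the molecular graph: every N–H/O–H/S–H hydrogen
is a donor site, every N/O/S with an available lone pair an acceptor
(amide nitrogens, pyrrole-type NH nitrogens and N⁺ are excluded). Each
site gets a category from a fixed, closed taxonomy (six donor, seven
acceptor categories) with documented precedence: carboxylic OH before
generic hydroxyl, amide NH before aromatic NH before amine NH.

An observation is a donor–acceptor pair labelled formed/not formed by the
geometric criterion: D–A distance ≤ vdW(D) + vdW(A) + 0.1 Å **and**
D–H···A angle > 120°. Bifurcated donors yield one observation per acceptor
reached. Extraction from multi-molecule clusters prefilters at 5 Å D–A,
comfortably above any vdW sum + 0.1 Å in the Bondi table.

The model is logistic: π = exp(α + Σχβ)/(1 + exp(α + Σχβ)), fitted by
Newton/IRLS on features [competition, donor steric density, acceptor
steric density, one-hot donor category, one-hot acceptor category, donor
aromaticity, acceptor aromaticity]. The four descriptor functions have no
published functional forms, so concrete defaults are defined and
unit-tested here: competition = acceptors/(donor H + acceptors) over the
system's sites; steric density = heavy atoms within 3.5 Å of the site atom
(excluding atoms ≤ 2 bonds away) / 10; aromaticity is binary (site atom
aromatic or bonded to an aromatic atom). A small L2 penalty (default 1e-6,
never on the intercept) guards against quasi-separation on the closed
taxonomy; the one-hot blocks are deliberately kept full-rank-deficient and
resolved by the penalty rather than by dropping reference levels, which
keeps coefficients symmetric in the categories. A zero-penalty fit that
fails to stabilise raises an error suggesting regularisation. On
intercept-only data the fit reproduces the closed-form logit of the raw
rate to 1e-6, and on synthetic data with known coefficients (n = 5000) it
recovers them within 3 standard errors.

**Training data.** The original model was trained on curated crystal-contact
data that is not redistributable; this package fits the same mechanism to
user-supplied observation CSVs or to the synthetic generator's output. The
shipped model mechanism is faithful; its coefficients are not a
reproduction of any published fit, and propensity values from synthetic
training should be read comparatively, not as literal probabilities.

**Multi-component score** = max hetero propensity − max homo propensity,
with the reported direction the class of the single most likely pairing
(ties resolved toward hetero, then lowest atom indices, making the score
independent of enumeration order). The "max interaction" reported alongside
is the raw maximum; whether the published quantity conditions on direction
is ambiguous, so the direction is reported separately.

## Synthetic data: what it does and does not show

The generator produces (i) logistic observations with chosen (α, β) and
simple feature distributions, (ii) planted hydrogen-bond clusters —
methanol donating to trimethylamine acceptors at prescribed D–A distances
and D–H···A angles, the amine chosen because it has no donor hydrogens, so
the planted contacts are the only possible observation pairs — and (iii)
toy molecule series with monotone FPV (hexane → polyols) or monotone S/L
(linear acenes, rigid so the trend is conformation-independent).

Passing tests on these inputs demonstrates that the machinery (detection
geometry, likelihood optimisation, descriptor monotonicity, ranking
determinism) is correct. It does **not** demonstrate that screening
predictions transfer to real crystallisation outcomes: synthetic features
are drawn independently, whereas real site descriptors are correlated;
planted clusters lack packing context; and toy series lack the
polarity–shape trade-offs of drug-like molecules. The packaged tables of
the source study's printed screening results are included precisely so the
reporting machinery can be checked against real published numbers.

## Numerical choices and degenerate inputs

* Voxel resolution 0.2 Å default (error if coarser than the smallest
  radius); volumes are monotone under atom addition and rigid-motion
  invariant within grid re-sampling tolerance (≤ 2 %).
* Box search: 10° coarse grid over α ∈ [0°, 90°), β ∈ [0°, 180°],
  γ ∈ [0°, 360°) — a covering domain after quotienting by the box's
  quarter-turn symmetry about z — then Nelder–Mead refinement.
* IRLS: convergence on coefficient step < 1e-10, cap 100 iterations;
  weights floored at 1e-10.
* Multi-fragment inputs (salts, mixtures) are rejected at read time rather
  than silently keeping the largest fragment.
* Coformers passing zero conformations are reported "not rankable" (their
  optimal deviancy is undefined by construction) and sort after ranked
  entries with `rank = NA`.
* Rigid molecules returning fewer conformers than requested produce a
  warning, not an error; the screen proceeds on the distinct set.

## Problem sizes used by the packaged checks

The test-suite and the acceptance script run the full funnel on the
shipped 10-coformer library against the synthetic flexible API stand-in
with 3-conformer ensembles at 0.3 Å voxel resolution, fit recovery models
at n = 5000 × 3 seeds, compare the hydrogen-bond detector with a
brute-force oracle on 1000 random geometries, and compare the box search
with an exhaustive 2° rotation grid on 20 random ≤ 8-atom clusters. These
sizes were chosen as the smallest that exercise every code path with
stable statistics.

## Known limitations

* The synthetic API stand-in (`pf4_like_synthetic`) is not the published
  API; its printed reference dipole (6.434 D) is metadata only.
* Geometric cutoffs and HBP coefficients are study-specific inputs, not
  package constants.
* The geometry check uses static windows, not crystallographic
  distributions; torsions are effectively unconstrained by default.
* The steric-density and competition functions are reasonable defaults
  behind a pluggable featuriser, not validated reproductions.
* No crystal-packing or lattice-energy reasoning: a high-ranking pair can
  still fail to cocrystallise, which is why the funnel ends in experimental
  screening rather than a prediction.
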