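---
title: "HDX-guided docking restraints, rescoring and allostery detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HDX-guided docking restraints, rescoring and allostery detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdock)
```

## Scope and assumptions

`hdxdock` operates downstream of two experiments it does not perform:
a docking run that produced an ensemble of rigid-body antibody–antigen
poses with a base interface energy per pose, and a differential HDX-MS
experiment that produced peptide-level deuterium-uptake time courses
(or, directly, a list of HDX-interacting peptides). The package
assumes:

* residue identity is shared between all poses and the reference via
  author numbering `(chain, resno, insertion code)`; no renumbering is
  ever performed, because HDX peptide spans arrive in antigen author
  numbering. Peptide spans are inclusive on both ends.
* the chain partition into antibody and antigen is total: a pose
  containing a chain in neither set is rejected with a diagnostic, not
  silently trimmed.
* geometry is Cα-level for restraints and RMSDs, heavy-atom-level for
  interface and contact definitions. Hydrogens are parsed but flagged
  and excluded from every distance computation, since their presence
  is an artifact of the structure-preparation pipeline.
* alternate conformers collapse to the blank/'A' location, giving
  deterministic single-conformer geometry.

## The restraint and its parameters

An HDX-interacting peptide is turned into a distance restraint: at
least `k` of its eligible residues (non-proline when
`exclude_proline`, the default — proline has no exchangeable backbone
amide and thus carries no HDX signal) must place a Cα within `d` of
any CDR Cα. For each eligible residue we take its shortest Cα–Cα
distance to the CDR set; the effective distance `x` is the `k`-th
smallest of these per-residue minima, and the penalty is the
flat-harmonic `f(x) = max(x - d, 0)^2` (squared-Å). A model's HDX
score is the sum over peptides.

Tunable parameters, defaults, and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `d` | 10 | Å | most lenient of the supported stringency grid {5, 8, 10}; tighter thresholds penalize near-native poses when allosteric peptides are present |
| `k` | 1 | residues | grid {1, 2, 3}; at `k = 1` the effective distance is the global shortest Cα–Cα distance |
| `exclude_proline` | TRUE | — | no backbone amide, no HDX signal |
| `hdx_weight` | 4.5 | — | the selection weight at which top-model quality and enrichment improvements saturate without over-penalizing ensembles that contain allosteric peptides |
| `allostery_threshold` | 0.75 | weighted-score units | highest top-10 mean weighted HDX score observed for clean datasets; above it an allosteric peptide is inferred |
| `top_n` | 10 | models | standard final-selection size in docking benchmarks |

The `k > 1` penalty form is a design choice: published stringency
grids state only that 2–3 residues are "required" within threshold.
Penalizing the `k`-th smallest per-residue minimum through the same
flat harmonic is the minimal generalization that reduces exactly to
the `k = 1` form, keeps the penalty continuous in the coordinates, and
preserves the stringency ordering (penalty non-decreasing in `k`,
non-increasing in `d`), which the test suite asserts as a property.

Peptide residues absent from a model contribute only their present
residues (logged), rather than erroring: peptides mapped from
homologous antigen strains need not align residue-for-residue. A
peptide with *no* eligible residue (an all-proline span, or a span
entirely missing) is an error naming the peptide. If fewer than `k`
eligible residues exist, the largest available order statistic is used
with a log message; only the zero-eligible case is treated as fatal.

## Normalization and the combined score

Raw HDX scores live on squared-Å scale and interface energies on an
energy scale, so the HDX column is rescaled before combination:

```
scale  = (iface_high − iface_low) / (hdx_high − hdx_low)
normalized = scale × hdx_raw
combined   = weight × normalized + interface_score
```

where `*_high`/`*_low` are the means of the highest and lowest
`ceiling(0.10 · N)` values of each column (minimum one value each; the
rounding rule is a package choice, as published descriptions do not
state one). Three degenerate-input conventions:

* all raw penalties (trimmed-)equal — most commonly all zero — makes
  the scale undefined; every normalized value is set to 0 and the
  combined score gracefully reduces to the base score. The scale is
  reported as `NA` with a log message.
* ranking ties are broken lexicographically by model id, so output
  order is reproducible across platforms and hash orders.
* an empty HDX peptide list degrades the whole pipeline to
  base-score-only behaviour rather than erroring.

Because penalties are non-negative, the HDX term can only disfavor a
model; a pose satisfying every restraint keeps its base score exactly.
A separate diagnostic normalization, `percent_normalize()`, expresses
penalty totals as a percentage of the ensemble maximum (all-zero input
maps to all zeros) for comparing restraint stringencies across
ensembles.

## Model quality and ensemble metrics

`compute_quality()` implements the CAPRI-style metrics with the
antigen as receptor and the antibody as ligand:

* **fnat** — fraction of reference inter-partner residue contacts (any
  heavy-atom pair < 5 Å, the CAPRI convention) reproduced by the
  model.
* **L-RMSD** — antibody Cα RMSD after least-squares superposition on
  the shared antigen Cαs.
* **iRMSD** — Cα RMSD over the reference-defined interface residues
  (any heavy atom within 10 Å of the partner), superposing on exactly
  those Cαs. Defining the interface on the reference only, and
  fitting on interface Cαs rather than the whole receptor, is the
  standard CAPRI practice; the choice is logged here because published
  descriptions say only "after superposition".

Superposition is the Kabsch algorithm via SVD with the reflection
corrected to a proper rotation; the test suite checks it against both
a direct numerical minimizer and an independent library implementation
to 1e-4 Å and asserts rigid-motion invariance of the metrics to 1e-6.

Class assignment checks high, then medium, then acceptable with
cumulative upper-bound windows (`fnat ≥ 0.5` and `L-RMSD ≤ 1` or
`iRMSD ≤ 1`; `fnat ≥ 0.3` and `≤ 5` / `≤ 2`; `fnat ≥ 0.1` and `≤ 10` /
`≤ 4`), so a model meeting a higher class's criteria always takes the
higher class; "near-native" means acceptable or better, and a docking
run is "successful" when at least one near-native model ranks in the
top 10. Enrichment follows `(TP/(TP+FP)) × ((P+N)/P)` with positives
the top 10 % by score and true positives those also in the ensemble-
wide top 10 % by iRMSD — maximum 10, random expectation 1. KS
comparisons use the asymptotic two-sample test.

## Allostery detection

The diagnostic quantity is the mean weighted HDX score
(`weight × normalized`) over the current top-10. Above the 0.75
threshold the dataset is flagged, and a leave-one-out scan excludes
each peptide in turn: raw totals are recomputed without it, the
normalization is redone on the reduced column (exclusion changes the
HDX range, so a new scale is required), models are re-ranked, and the
new top-10 mean is recorded. The argmin peptide is peeled off and the
loop repeats while the mean stays above threshold and at least two
peptides remain — with a single peptide, exclusion would empty the
restraint set and the metric is undefined. Rescoring-only is the
default; re-docking with the reduced restraint set after each
identification is available through the sampler but is not required
by the diagnostic.

The metric has a documented failure mode, reproduced deliberately by
the `masked` fixture: when the base score itself favors decoys that
happen to satisfy the allosteric restraint (an energy funnel sitting
off-epitope, with the allosteric peptide only slightly beyond
threshold), the top-10 carry near-zero HDX penalties and the dataset
is *not* flagged despite containing an allosteric peptide. Tests
assert this outcome as expected behaviour, not as a defect.

## The uptake significance filter

Protection is `diff_t = unbound_mean_t − bound_mean_t` (positive when
binding protects). A peptide is HDX-interacting iff some timepoint has
`diff_t ≥ 0.5 Da` **and** `diff_t ≥ 3 × pooled SD` (the two state SDs
combined in quadrature), and the signed sum of diffs over all
timepoints exceeds 1.1 Da. Two readings were open: the "±3 SD" clause
is implemented as a conjunction with the absolute gate (the stricter
reading), and the SD is pooled across states rather than per-state;
both choices are exposed as arguments. The cumulative sum is signed,
so mixed protection/deprotection can cancel, and deprotection alone
can never flag a peptide. The filter is monotone: raising any gate
never flags more peptides (a property test).

## The toy sampler

The Metropolis sampler exists to demonstrate the restraint-guided
acceptance contract, not to model physics. The antibody moves as a
rigid body about its Cα centroid; the antigen is fixed. A scrambled
start displaces the antibody by exactly 10 Å in a random direction
(with a 60° scramble rotation), assigns a uniformly random
orientation, and applies one Gaussian perturbation; moves are Gaussian
(3 Å per axis, 8° about a uniform axis). The coarse score counts
inter-partner Cα pairs: +10 per pair under 3.5 Å (clash), −1 per pair
in [3.5, 8) Å (contact); its weights and shells are fixture-tuned
constants, and the score is declared non-physical. With HDX guidance
the acceptance total is `coarse + 1.0 × hdx_penalty`; the temperature
default is 1.0 in coarse-score units (an energy-function-internal
quantity with no transferable published value, hence config-exposed).
Trajectories are bit-reproducible from the config seed. The rotation
perturbation distribution (uniform axis, Gaussian angle) is a package
choice, as is moving only the antibody — displacing one partner is
equivalent to the published scramble of both up to a global rigid
transform, which every implemented metric ignores.

## What the fixtures emulate, and what they do not

`make_toy_complex()` builds idealized Cα-trace chains on parallel
lines 6 Å apart at 3.8 Å spacing, with a Cβ pseudo-atom per residue
bridging the interface to 2.8 Å (so native contacts exist for fnat)
and a backbone O. Planted interacting peptides sit directly under the
CDR segments (effective distance ≈ 6 Å); planted allosteric peptides
are offset along the chain so their reference effective distance is at
least the requested gap (defaults: 30 Å, and 36 Å for a second — the
second gap is chosen beyond the decoy generator's 20 Å maximum
displacement so no reachable pose can satisfy it, which keeps the
leave-one-out signal clean). A single proline is planted inside a
peptide to exercise the exclusion rule, and 0.2 Å coordinate jitter
avoids exact-degeneracy artifacts. `make_decoy_ensemble()` perturbs
the antibody rigidly (displacement `20 · u^1.5` Å for uniform `u`,
concentrating decoys near-native, plus a small rotation), measures
each decoy's iRMSD with the package's own evaluation module (an
internal cross-check of the superposition code), and assigns base
scores `−30 + 0.8 × iRMSD + noise` REU so score-ranking quality is
tunable; the `masked` scenario adds a biased sub-population displaced
along the chain axis with an 8 REU bonus, the funnel-off-epitope
failure mode. `make_uptake_table()` plants protection of 0.8/1.0 Da
at 100 s/1000 s against 0.05 Da SDs — clearing every gate — and
sub-threshold 0.1/0.15 Da differences elsewhere.

These fixtures are deliberately minimal. They do not emulate real
protein topology, side chains, hemagglutinin geometry, realistic
uptake kinetics, back-exchange, or correlated experimental noise.
Passing tests therefore demonstrate the *algorithms* — penalty
geometry, normalization arithmetic, ranking, recovery of planted
structure under the stated noise models — not performance on real
ensembles, which depends on the docking program's energy function and
sampling quality.

## Problem sizes and numerical conventions

The test suite runs at desk scale: ensembles of 25–200 decoys for
oracle-equivalence and recovery tests, 1000 synthetic score/iRMSD
pairs for enrichment extremes (200 random-permutation seeds for the
unit-expectation check), 20 seeded fixtures for allostery recovery,
and 200 Metropolis runs of 500 steps per arm for the sampling-shift
property; the full suite completes in a few minutes on one CPU.
Other conventions: distances are plain Euclidean (no periodic or
symmetry images); cross-distance matrices clamp tiny negative values
from floating-point cancellation before the square root; score-row
invariants hold to 1e-9; KS statistics are checked against an
exhaustive ECDF scan to 1e-12; rigid-motion invariance of penalties
and RMSD metrics is asserted to 1e-6.

## Known limitations

* Restraints are Cα-only with no solvent-accessibility weighting and
  no residue-level exchange rates; all residues of a peptide are
  treated alike.
* The base interface energy is an input, never computed: the package
  contains no physical energy function, and its coarse sampler score
  must not be interpreted as one.
* The allostery diagnostic inherits the failure mode described above
  and assumes at least two peptides.
* CDR definitions are inputs; no automatic numbering-scheme detection
  is attempted. mmCIF input is not supported.
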