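---
title: "Predicting protein-protein interface residues with radt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interface residues with radt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radt)
library(dplyr)
```

## The problem

Transient protein-protein interactions — reversible associations between
proteins that are stable on their own — drive most cellular signalling, and
the residues that form their binding interfaces are prime therapeutic
targets. Given only the crystal structure of an unbound monomer, the task
is to predict, residue by residue, which positions would participate in an
interface. `radt` implements a complete machine-learning treatment of this
problem: dataset curation from PDB-format files, geometric interface
labelling, per-residue feature computation, class rebalancing, an
Alternating Decision Tree (AD-Tree) classifier evaluated by
leave-one-protein-out cross-validation, and feature-subset selection by a
genetic algorithm accelerated with Hoeffding racing.

## Dataset construction

**Monomers and complexes.** A structure with exactly one `COMPND` molecule
entry is treated as a monomer (an unbound deposit, possibly with several
copies of the same chain); a structure with more than one entry is a
complex. The monomer is represented by its longest chain, ties broken by
the lowest summed B-factor, then file order (`select_representative_chain()`).

**Quality filters** (`apply_curation_filters()`). Monomers are kept when:
resolution ≤ 3.5 Å; ≤ 5 chains; every chain 100–800 standard residues with
a between-chain length SD ≤ 5; ≤ 1000 `CONECT` and ≤ 100 `SSBOND` records
(removing ligand-laced and unusually cross-linked structures); B-factors
present on all atoms (they are used directly as a feature); no nucleotide
residues; no antibody complexes (keyword heuristic on the header). All
rules are evaluated — a verdict always carries the complete list of failed
rules. Chain lengths count standard amino acids only, since that is what
the downstream feature table contains.

**Deduplication.** Monomers sharing *more than* 70% global sequence
identity are duplicates; a greedy first-kept pass in input order retains
one representative. Identity is computed with `Biostrings`' global
alignment under a deliberately plain scheme (match +1, mismatch 0, gap
open −10, gap extend −0.5), identical aligned positions divided by the
full alignment length including gaps. The dedup threshold is coarse, so
the scoring details rarely flip a decision; the scheme is configurable.

**Interface labelling** (`label_interface()`). Each monomer is aligned to
every chain of each complex; a chain matching at ≥ 80% identity
(inclusive) carries labels back to the monomer. A complex residue is
*interacting* iff any of its atoms lies within 4.5 Å (inclusive) of any
atom of a chain belonging to a *different* `COMPND` entity. Labels
transfer through the residue map of identical aligned positions; a
labelling is rejected when fewer than 90% of the monomer's residues could
be mapped, or when the complex has no inter-entity contact at all. Labels
from several complexes combine as a logical OR. Hydrogens participate in
the contact scan when present; crystal structures rarely include them.

The 90% validation rule is stated in terms of "residue identity between
the complex and monomer representations"; we read it as *coverage of the
monomer chain* by mapped identical residues (the alternative — identity
over mapped positions only — would pass chains with large unmapped gaps).

**Interface sites and the NI subsets.** Interacting residues are clustered
into spatially contiguous *sites* by single linkage: two residues link iff
any inter-atomic distance is ≤ 6 Å (a conservative patch-contiguity value;
configurable). The site rate is `100 × sites / chain length`; proteins
with rate ≥ 1 form the NI1 subset ("at least one interface site per
100-residue domain"), rate ≥ 2 the NI2 subset. The continuous rate form is
scale-stable and matches the subset naming; a per-100-residue-window count
is the other admissible reading. Better-labelled subsets matter because a
residue not seen in any complex is *unknown*, not negative — enforcing a
minimum site rate reduces hidden-interface noise in the test labels.

Interfaces generated from `BIOMT` biological-assembly transforms
(`expand_biomt()`) are supported by running the same labelling on the
expanded structure, but are kept out of the default channel.

## Residue features

Features are computed for **every** standard residue, buried or exposed —
buried residues can become exposed on binding and influence their
neighbourhood.

| feature | definition | units / range |
|---|---|---|
| `relSESA` | residue accessible area / reference maximum area | ~[0, 1.5] |
| `protrusion` | CX index: empty/occupied volume in a 10 Å sphere | [0, 100] |
| `roughness` | neighbourhood area / smooth footprint area | ≥ 0, ~1 smooth |
| `density` | neighbourhood atoms per Å² of neighbourhood area | atoms/Å² |
| `curvature` | signed 1/R of sphere fitted to neighbourhood | 1/Å |
| `hydrophobicity` | Fauchère–Pliska π value by residue type | kcal/mol |
| `propensity` | ln(f_interface / f_all) from training labels | log-odds |
| `esolv` | Σ atomic solvation parameter × atom area | kcal/mol |
| `bfactor`, `bfactor_norm` | residue mean B-factor, raw and per-structure z-score | Å², SD |
| `epot` | screened Coulomb potential at side-chain centroid | model units |
| `scorecons`, `rate4site`, `disorder` | injected from external files | as supplied |

**Surface area.** Accessible area is computed by deterministic sphere
sampling (a Fibonacci point set, 960 points per atom by default) on
spheres of radius r_vdw + 1.4 Å. This replaces a solvent-*excluded*
(Connolly) surface from an external triangulation engine with a
solvent-*accessible* one; the relative form (`relSESA`) preserves the
feature's discriminative role, and the substitution is an approximation we
make explicitly. Reference maximum areas are computed once per
configuration by running the *same* engine on internally built extended
Gly-X-Gly tripeptides (`reference_max_areas()`). The tripeptide geometry is
idealised — correct heavy-atom composition per side chain, coarse
coordinates — so `relSESA` is exactly 1 on the reference conformation by
construction, and ratios are self-consistent across residue types.

**Residue-local features.** Each residue's neighbourhood is its nearest
residues by centroid distance within 8 Å, clipped to between 2 and 6
neighbours; residues with fewer than 2 neighbours have their neighbourhood
features masked rather than silently filled. Roughness divides the
neighbourhood's summed atomic area by the area of its smooth reference —
the disc footprint of the centroids projected onto their best-fit plane,
inflated by the mean probe-extended atom radius. The footprint is
insensitive to spikes perpendicular to the surface, so added spike atoms
raise roughness monotonically (the property we test); its absolute scale
on sparse synthetic shells is only ~O(1). Curvature is the inverse radius
of an algebraic least-squares sphere fit to the centroids, signed positive
when the patch is convex outward (fit centre on the protein-interior side);
a rank-deficient fit (coplanar centroids) is reported as exactly 0.

**Electrostatics.** The Poisson–Boltzmann grid of the original tool chain
is replaced by a Debye–Hückel screened Coulomb sum with integer side-chain
charges (+1 LYS/ARG, −1 ASP/GLU, +0.5 HIS), ε = 80 and λ_D = 8 Å,
evaluated at each residue's side-chain centroid excluding its own charge.
This keeps the feature desk-scale and dependency-free; the provider is
pluggable if a true PB solution is available.

**Injected features.** Conservation, evolutionary rate shift and disorder
have no credible internal approximation, so they are file-injection only
(`load_external_features()`): a TSV keyed by residue, with duplicate keys
and non-numeric values rejected loudly and unmatched residues masked.

## Class imbalance

Only a small fraction of residues are labelled interacting (about 13% in a
broadly curated set, 26% in an NI1-style subset), which biases learners
toward the majority class. `undersample()` removes majority-class
instances at random, without replacement, until the positive fraction is
within one instance of a target; the minority class is never touched and
under-sampling is applied to *training folds only* — test proteins are
always evaluated unmodified. `distribution_sweep()` re-runs
cross-validation across targets from 30% to 70% and reports where the true
positive and true negative rates cross (linearly interpolated), the point
of balanced prediction. The rounding rule is
`negatives = round(positives·(1−f)/f)`.

## The AD-Tree learner

An alternating decision tree is a boosted structure of *splitter* nodes
(feature ≤ threshold) and real-valued *prediction* nodes; an instance's
margin is the sum of prediction values along **all** paths whose
conditions it satisfies, and the predicted class is the margin sign (zero
counts as positive). Training (`train_adtree()`):

* weights start uniform; the root value is ½·ln(W₊/W₋), after which
  weights update by e^(−y·value);
* each boosting iteration exhaustively searches every (prediction node,
  feature, threshold at midpoints of observed values within the node's
  reach set) and keeps the candidate minimising
  Z = 2(√(W₊ʸᵉˢW₋ʸᵉˢ) + √(W₊ⁿᵒW₋ⁿᵒ)) + W(unreached);
* new prediction values are ½·ln((W₊+ε)/(W₋+ε)) with ε = 1/n — the
  smoothing changes margins, so it is part of the contract;
* ties break deterministically: lowest feature index, then lowest
  threshold, then earliest prediction node. A numeric tolerance of 1e-12
  treats analytically-equal Z values as ties.

Ten boosting iterations is the default, matching the configuration used
for the final predictor. The implementation is validated against an
exhaustive-search oracle on small instances, and its Z trace is checked to
be non-increasing. Alternative classifiers plug in through a minimal
adapter contract (`fit(instances)` / `margin(model, instances)`);
`logistic_learner()` demonstrates it and `adtree_learner()` is the
default. Models serialise to JSON at full precision, so scores round-trip
exactly.

## Evaluation

`classification_stats()` computes TPr (sensitivity), TNr (specificity),
precision, MCC and F1 from confusion counts. Degenerate denominators —
frequent in per-protein scores of small proteins — are reported as 0 with
a `degenerate` flag rather than NaN, so per-protein averages stay defined.

`lopo_cv()` performs leave-one-protein-out cross-validation: every fold
holds out *all* residue instances of one protein, trains on the rest
(optionally under-sampled), and scores the held-out protein; the headline
score is the mean per-protein MCC. The fold structure is asserted
leak-free in the tests with a probe learner that refuses to score a
protein it saw in training.

`iterative_removal()` repeatedly removes the worst-scoring protein
(lexicographic tie-break) and records the mean MCC of the remainder,
optionally tracking a fixed subset of proteins — the tool for separating
label-noise effects from training-set over-specialisation.

`wilcoxon_signed_rank()` implements the paired signed-rank test exactly as
used for method comparison: zero differences dropped, average ranks on
ties, W = sum of signed ranks, two-sided p from the normal approximation
with tie correction; an exact 2ⁿ enumeration mode (default for n ≤ 12) is
the oracle in our tests. `pearson_feature_correlation()` gives the
point-biserial correlation of a feature with the binary label.

`summarise_metrics()` / `compare_to_baseline()` / `summarise_comparison()`
reproduce the conventional summary arithmetic of method-comparison tables.
One convention deserves a note: the "average % improvement" of a baseline
over a panel is quoted as the *ratio of means* (100·mean(Δ)/mean(value)),
not the mean of per-method ratios, while the median column is the ordinary
median of per-method values; `summarise_comparison()` implements exactly
this.

## Feature-subset selection

`ga_search()` evolves feature masks with uniform crossover (rate 0.8),
per-bit mutation (rate 1/k) and an explicit elite. Fitness is the mean
per-protein MCC from leave-one-protein-out evaluation. Because each
fitness evaluation is a full cross-validation, every generation is *raced*
against the elite (`race()`): folds are evaluated in a fixed seeded order
shared by all candidates (paired racing keeps comparisons low-variance),
and a candidate is eliminated as soon as its Hoeffding upper confidence
bound falls below the elite's lower bound. With the total fold count N
known, the classic optimistic bound x̄ + ε is tightened to the weighted
form (n/N)·x̄ + ((N−n)/N)·(x̄+ε), which collapses to the empirical mean at
n = N; the elite's lower bound mirrors the same weighting downward (the
mirror is our choice; only the upper bound's form is prescribed). ε uses
range R = 2 (MCC lives in [−1, 1]) and δ = 0.05 by default; δ = 0 makes
the bounds infinite, so racing degenerates to exact full evaluation — an
invariant the tests exploit. GA hyper-parameters (population 32,
generations 20, elitism 1) are conventional defaults, all configurable,
and `ga_feature_tally()` aggregates selections across repeated seeded runs
into a per-feature count.

## Synthetic fixtures: what they do and do not show

`make_toy_complex()` builds CA-only two-entity complexes in which a
contiguous patch of residues sits at 3.8 Å across chains and everything
else beyond 6 Å — by construction no atom pair falls in the ambiguous
4.4–6.0 Å band, so the 4.5 Å rule must recover exactly the planted patch.
`make_synth_structure()` provides helix, plane and sphere-shell geometries
for the analytic feature limits (curvature 1/R on a sphere, 0 on a plane).
`make_planted_instances()` draws informative features from
class-conditional normals N(0,1) vs N(d,1) and noise features from N(0,1),
with exact per-protein positive counts and per-protein grouping preserved
for cross-validation.

Default generator conditions, chosen once: 12 proteins × 40 residues, two
informative features at effect size d = 2 SD, six noise features, positive
fraction 0.26 (the interacting-residue rate observed in a well-labelled
NI1-style subset). Two experiments use their own stated conditions:

* the **class-distribution sweep** runs on a symmetric generator
  (positive fraction 0.5) at effect size 1.0 with 24 proteins × 60
  residues — at d = 2 both rates saturate near 0.9 and the crossing is
  noise-dominated, while d = 1 reproduces the 0.3–0.9 dynamic range over
  which the sweep's monotone trade-off is visible, and the larger set
  stabilises the interpolated crossing (expected at 0.5 by symmetry);
* the **genetic-search recovery** experiment uses 6 proteins × 30
  residues with 1 informative + 7 noise features at d = 2, AD-Trees with
  3 boosting iterations, population 8 and 4 generations — small enough to
  run in seconds, strong enough that the informative feature should be
  selected in essentially every seeded run.

These fixtures validate the *machinery*: geometry-exact labelling, metric
arithmetic, fold hygiene, boosting correctness, racing safety and
parameter recovery. They do not emulate real protein surfaces (no
side-chain packing, no crystal contacts, no correlated features, Gaussian
rather than heavy-tailed feature noise), so passing tests demonstrate
correctness of the implementation, not field performance on real
structures — reproducing published benchmark scores would require the
original structure snapshot and external feature tools.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties by alternate-location
  character order.
* Residue identity is (chain, author seq number, insertion code) — no
  renumbering, so labels always map back to source files.
* Sphere sampling is deterministic (fixed point set): identical input
  gives identical areas; rotation invariance holds only to sampling
  tolerance (~2–5%), closed-form features to 1e-6.
* MCC/precision/F1 denominators of zero → 0 with a flag (see above).
* Margin exactly 0 → positive class.
* `undersample` errors on a missing class; `train_adtree` errors on
  single-class input and stops early (recorded) if no feature admits a
  split.
* Connection/disulphide counts are raw `CONECT`/`SSBOND` record counts;
  the counting rule is a documented package convention.
* Nucleotide presence flags any standard nucleotide residue name, polymer
  or ligand — the conservative reading.

## Pipeline and configuration

`run_pipeline()` chains synth → curate → label → featurize → cv from a
single YAML configuration with per-stage sections (all contact, filter and
learner thresholds appear as named keys with the defaults above). Each
stage writes a manifest with a configuration hash chained from upstream
stages: re-running with an unchanged configuration skips stages, and
changing any upstream key re-runs everything downstream. A thin
command-line wrapper (`inst/cli/radt.R`) exposes `parse`, `synth` and
`run` subcommands; the R functions are the primary interface.

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(
  seed = 1, out_dir = "radt_run",
  synth = list(n_proteins = 6, n_residues = 30, patch_size = 4),
  cv = list(iterations = 10, target_positive_fraction = 0.5)))
res
```

## Known limitations

* Accessible (not solvent-excluded) surface areas; idealised reference
  tripeptides; screened-Coulomb (not Poisson–Boltzmann) electrostatics —
  each documented above as an explicit approximation.
* First NMR model only; no mmCIF; no chemical-component dictionary (only
  MSE is recognised as a modified standard residue).
* Interface sites ignore crystal-packing versus biological-contact
  distinctions beyond the separate BIOMT channel.
* The propensity feature is estimated from whatever training labels are
  supplied and is therefore circular if evaluated on its own training set;
  use it only inside cross-validation, where it is re-estimated per fold
  by the caller if desired.
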