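---
title: "Predicting interface hot spots from structure and sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting interface hot spots from structure and sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

## The problem and the model

Alanine-scanning experiments show that binding free energy at
protein–protein interfaces is concentrated in a few *hot-spot* residues:
positions where mutation to alanine costs ΔΔG ≥ 1 kcal/mol (≥ 2 kcal/mol
under the stricter convention). `hotspotr` treats hot-spot identification
as binary classification over per-residue feature vectors and trains a
soft-margin SVM with the radial basis kernel,

$$ f(x) = \sum_i \alpha_i y_i \exp(-\gamma \lVert x - x_i \rVert^2) + b, $$

predicting *hot spot* when $f(x) \ge 0$ (a score of exactly zero is assigned
to the positive class by convention). Feature vectors are assembled from six
groups that can be toggled per model: structure-derived ASA (5 columns) and
biochemical contacts (3), and sequence-derived physicochemical scales (6),
normalised PSSM (20), conservation grade (1) and sequence entropy (1). A
purely sequence-based model uses {Phy, PSSM, ECS, SE} (28 columns); a purely
structural one uses {Phy, ASA, BC}.

## Feature definitions and their parameters

**Solvent accessibility.** SASA is computed by Shrake–Rupley sampling:
each heavy atom's solvent-expanded sphere (van der Waals radius + 1.4 Å
probe) carries a deterministic golden-spiral lattice of test points
(default 960/atom), and the accessible fraction times the sphere area gives
the atomic SASA. The isolated-atom quadrature error is below 1% at 960
points and decreases as 1/n. Per-residue areas are sums of atomic areas.
ΔASA is the monomer-state minus complex-state residue area at identical
coordinates; values in (−0.1, 0) Å² are quadrature noise and clamp to zero.
A residue with ΔASA ≥ 1 Å² is an *interface residue*; only interface
residues enter datasets. ΔASA% is undefined when the monomer-state area is
zero and is propagated as missing, not as 0. relASA divides the
complex-state area by the residue type's area in an extended ALA-X-ALA
tripeptide (embedded table; all-atom accessibilities — whether side-chain-only
accessibility would be preferable is untestable without the original outputs,
so all-atom is used throughout). Van der Waals radii are a per-element
table (C 1.76, N 1.65, O 1.40, S 1.85 Å, …) with per-atom-name overrides
available where the aliphatic/aromatic carbon split matters.

**Contacts.** All three counters pair atoms across the interface only.
Salt bridges: formally charged side-chain atoms (LYS NZ; ARG NE/NH1/NH2;
ASP OD1/OD2; GLU OE1/OE2; HIS ND1/NE2 counted positive by default, with a
flag to exclude histidine) of opposite sign within 7 Å. Hydrogen bonds use
a declared heavy-atom geometric criterion — donor–acceptor distance ≤ 3.5 Å
and antecedent–donor–acceptor angle ≥ 90° — with donors/acceptors from an
embedded per-residue table; crystal structures at typical resolution lack
hydrogens, so no hydrogen positions are ever required, and a pair in which
both atoms can donate and accept (e.g. two serine hydroxyls) counts once
per orientation. Atomic contacts are heavy-atom pairs with
$d < r_i + r_j + s$, slack $s = 0.25$ Å by default: a distance-overlap
reading of contact detection that is stated prominently here because the
raw "0.25 Å distance" convention it replaces is not physically meaningful.
Neighbour search uses a uniform cell grid; the test suite checks it against
an exhaustive all-pairs scan.

**Sequence features.** The six physicochemical scales are pinned to AAindex
accessions (KYTJ820101 hydrophobicity, HOPT810101 hydrophilicity,
GRAR740102 polarity, CHAM820101 polarizability, CHOP780202 β-sheet
propensity for the propensity slot, JANJ780101 average accessible surface
area). Raw PSI-BLAST PSSM scores x map to (0,1) by the logistic
$1/(1+e^{-x})$ — strictly monotone with midpoint 0.5 — which is the
normalisation dialect adopted here for profile scores. Sequence entropy of
an alignment column is $100 \cdot H/\ln 20$ with
$H = -\sum_a p_a \ln p_a$ over the 20 amino acids, gaps excluded, so 0 is
fully conserved and 100 maximally variable; a 50/50 two-residue column
gives $100\ln 2/\ln 20 = 23.14$. Conservation grades use the ConSurf 1–9
scale (9 = conserved): grade files are parsed and passed through, and when
only an MSA is available a fallback estimator bins per-column entropy into
nine quantile classes of that protein, inverted. The fallback is a
monotone transform of entropy, not a phylogenetic rate — it ignores tree
structure entirely — and its provenance is recorded on the output so
downstream tables can distinguish the two sources.

## Labels, datasets, evaluation

ΔΔG labels are inclusive: hot spot ⇔ ΔΔG ≥ threshold, default 1 kcal/mol.
Categorical BID labels map Strong and Intermediate to hot spots and the
remaining four categories to non-hot spots. `balance_lowest_ddg()`
implements the balanced design used with the 2 kcal/mol definition (all hot
spots plus the equally many lowest-ΔΔG non-hot spots; ties break
lexicographically by residue key). Antibody/non-antibody dataset variants
are split on an explicit per-complex flag, since antigen–antibody
complexes dilute conservation signal (antibody paratopes are selected for
variability).

Missing feature cells (no PSSM coverage, unknown residue type) are imputed
with the column mean and the affected rows flagged; this keeps the kernel
matrix finite without inventing signal.

Model selection is a seeded grid search (defaults C ∈ 2^{−5..15},
γ ∈ 2^{−15..3}, step 2 in the exponent) maximising mean cross-validated F1,
ties resolved toward the smallest C then the smallest γ — deterministic by
construction. Features are z-scored with parameters fit on training data
only and refit inside every CV fold, because the RBF kernel is
scale-sensitive. In `cross_validate()` the (C, γ) pair is chosen once on
the full data with the same seeded folds and then each fold is refit at
that pair; fully nested per-fold selection would multiply cost tenfold
while estimating the same operating point, and the single-selection design
matches the usual "grid search, then 10-fold CV" protocol. Reported CV
metrics pool confusion counts over folds (per-fold F1 values are returned
alongside). ROC curves sweep the decision-score thresholds with tied
scores grouped, so the trapezoidal AUC equals the Mann–Whitney
$U/(n^+ n^-)$ statistic exactly; decision values, not calibrated
probabilities, are used as scores. Trained models persist to JSON with all
numerics encoded as hexadecimal floating point, so a reloaded model
reproduces scores bit-identically.

The random baseline scores a uniformly random fixed-size positive subset
against fixed labels. With 182 predicted and 182 true positives among 377
residues, TP is hypergeometric and P = R = TP/182, so
E[F1] = E[TP]/182 = 182/377 ≈ 0.483 — the closed form the simulation is
checked against. Group comparisons (e.g. conservation in hot vs non-hot
spots) default to Welch's t-test, with Wilcoxon rank-sum as the
distribution-free alternative; the choice is echoed in the result.

## What the synthetic generators emulate

`make_toy_complex()` builds two extended chains facing each other across a
configurable tip-to-tip gap, with side-chain templates sufficient for the
geometric features (every feature here depends only on interatomic
distances, so idealized geometry loses nothing) and engineered
salt-bridge/H-bond placements at exact distances. A 100 Å gap gives the
zero-interface limit; note that burial persists until the tip gap exceeds
roughly $2(r_{vdw}+1.4)$ Å, since solvent-expanded spheres interact well
beyond van der Waals range. `make_synthetic_dataset()` plants a
standardized mean shift d on designated feature groups over unit-variance
Gaussian noise — the test model for classifier recovery, not a biological
claim: real feature distributions are heavier-tailed, correlated within
groups, and class overlap varies per complex. Passing recovery tests
therefore demonstrates the estimation machinery, not field performance on
real interfaces. `synthetic_training_mutations()` and
`synthetic_bid_mutations()` generate mutation tables whose *label margins*
(377 rows with 182 at ΔΔG ≥ 1 and 84 at ΔΔG ≥ 2; 148 rows with 80
Strong/Intermediate) match the published alanine-scanning study designs;
the individual residues and ΔΔG values are random within strata, and the
shipped CSVs under `inst/extdata/` are labelled synthetic accordingly.

## Numerical choices and degenerate inputs

* Altloc conformers: highest occupancy wins, ties to first-in-file —
  deterministic and standard practice.
* Zero-denominator metrics (no predicted positives, no true positives)
  return 0 with a degeneracy flag rather than NaN.
* Single-class datasets, empty feature combinations, unresolvable mutation
  keys, unknown elements without a fallback radius, and grades outside 1–9
  are hard errors; all-gap alignment columns and zero monomer-state ASA
  propagate as missing values.
* Fold assignment is stratified by class so near-balanced designs never
  produce single-class training folds; the assignment is a pure function
  of (labels, fold count, seed).
* Problem sizes in the test suite (toy complexes of 3–6 residues per
  chain, synthetic datasets of 100–400 rows, 8–20 CV seeds, 960-point SASA
  quadrature) were chosen as the smallest sizes at which each statistical
  property is stable; they are the package's reference conditions for its
  own checks.

## Known limitations

* Hydrogen-bond detection is a geometric heuristic on heavy atoms, not a
  network-optimisation method; counts on real structures will differ from
  optimizer-based tools in edge cases (bifurcated bonds, His tautomers).
* Conservation grades from the entropy fallback are not phylogenetic
  rates; use real ConSurf output where available.
* No mmCIF input, no symmetry-mate assembly, no sequence-redundancy
  culling; partner chain grouping must be supplied by the user.
* The shipped mutation tables are synthetic stand-ins that reproduce
  published margins, not the underlying experimental measurements; models
  trained on them demonstrate the pipeline, nothing biological.
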