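---
title: "posefrag: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{posefrag: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `posefrag`, the
assumptions behind them, the tunable parameters and their defaults, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Overview of the pipeline

`posefrag` predicts the binding pose of a query ligand by borrowing the
pose of a structurally similar crystallographic template ligand bound to
the same protein, refining it inside the rigid pocket, and scoring the
result with a four-metric confidence score. Poses passing the confidence
gate are exhaustively fragmented into a 3D-annotated fragment library
that supports interaction-fingerprint and attachment-vector queries.

The underlying assumption is the similarity principle: chemically similar
ligands tend to bind a given pocket in similar orientations. The method
inherits that principle's known failure mode — similar ligands that adopt
different binding modes — and performs only local refinement, never a
global pose search.

## Ligand standardization and conformers

*Protonation.* Ligands are standardized at pH 7.0 through Open Babel's
curated pH-transform rule table, so carboxylic acids are anionic and
aliphatic amines cationic. We deliberately delegate to that table rather
than maintaining a private rule set: it is widely used, versioned with
the Open Babel release pinned by the environment, and its behavior is
pinned by unit tests (acetate −1, methylammonium +1, benzene 0). Salts
and solvents are stripped to the largest organic component before
protonation; tautomers are left untouched (minimal intervention).

*Conformers.* Open Babel's conformer generator is not seedable, so
reproducible ensembles come from an in-package distance-geometry
embedder: bounds from a bond-length table, 1–3 distances from idealized
hybridization angles, van der Waals lower bounds, shortest-path upper
bounds with triangle smoothing; seeded metrization; classical metric MDS;
then deterministic MMFF94s minimization through `obabel`. Conformers are
pruned so every retained pair differs by ≥ 0.5 Å heavy-atom RMSD
(Kabsch-aligned), and the default ensemble size is 5 (over-generate by
4×, keep the lowest-energy conformer, then greedy max–min-RMSD
selection). The embedder does not enforce stereochemistry (stereoisomer
enumeration is out of scope); MMFF94s cleanup restores local geometry,
ring planarity and reasonable torsions.

## Template selection

Radius-2 circular fingerprints (ECFP-style iterative neighborhood
hashing; initial invariants: element, heavy degree, hydrogen count,
formal charge, ring membership, aromaticity) folded to 2048 bits. The
folded length is config-exposed because folding collisions perturb
Tanimoto values in the third decimal. The selection threshold is strict
(similarity > 0.3) and at most 3 templates are kept; ties are broken by
source structure id so results never depend on pool order.

## Field alignment

Every heavy atom carries a spherical Gaussian whose exponent is
κ/r²(vdW) with κ = ln 2, i.e. the density falls to half its maximum at
the van der Waals radius. The steric channel uses unit amplitudes; the
electrostatic channel reuses the same centers with Gasteiger partial
charges (hydrogen charges summed onto the bonded heavy atom) and its
cosine is clamped to [0,1]. Channels mix 0.5/0.5 by default; both κ and
the mix are `FieldModel` parameters because the original field
formulation this emulates is closed-source and unspecified at this level
of detail. The two-channel cosine normalization makes the similarity 1
for an exact self-overlay and invariant under a common rigid motion, both
pinned by tests, and the two-atom case has the closed form
exp(−d²·α/2) used as an analytic oracle.

Pose optimization is multi-start quasi-Newton (BFGS over a rotation
vector and translation): 12 deterministic starts from principal-axes
pairings plus seeded random rotations (default 4–8). A dense grid search
on a two-atom system serves as an optimizer oracle in the tests.
Returned poses are distinct at ≥ 0.5 Å heavy-atom RMSD, at most 3 per
template, so a query meets at most 9 candidate poses.

## Tethered refinement

The published protocol delegates refinement to an external tethered
docking program; `posefrag` implements a functionally equivalent local
optimization whose objective contains only pairwise-distance terms, so
gradients are analytic:

* bonded and 1–3 distances harmonically restrained to the input
  conformer (k = 300 and 60 kcal mol⁻¹ Å⁻²) — the conformer was just
  MMFF94s-minimized, so restraining to it preserves covalent geometry
  without re-implementing a force field;
* intramolecular and ligand–pocket Lennard-Jones (ε = 0.1 kcal mol⁻¹,
  σ from scaled van der Waals sums) and Coulomb with a
  distance-dependent dielectric (ε(r) = 4r), charged side-chain termini
  only on the protein side;
* harmonic tethers (default k = 10 kcal mol⁻¹ Å⁻², tolerance 0.5 Å) on
  the maximum common substructure atoms. "Fixed" is read as strongly
  restrained, not frozen, because refinement must be able to relieve
  clashes.

The MCS is connected, element- and bond-order-matched, found as a
maximum clique of the modular product graph with a deterministic
tie-break; below 3 heavy atoms the pose passes through untethered with a
flag. The protein is rigid (bit-identical before/after, tested). A
remaining ligand–protein heavy-atom contact below 2.0 Å sets a clash
flag rather than failing the pose.

## Scoring and the confidence score

* **IntDock** re-implements the published Vina empirical terms (two
  attractive Gaussians, quadratic repulsion, hydrophobic and H-bond
  ramps on the surface distance, published term weights, rotor penalty
  1/(1 + 0.05846·N_rot), 8 Å cutoff). No numeric identity with any
  external binary is claimed; the closed-form single-pair values are
  test oracles.
* **IntSim** extracts typed protein–ligand atom-pair counts within 6 Å
  (types: element, explicit valence, heavy neighbors, attached
  hydrogens, aromaticity, ring membership) and applies a pluggable
  estimator. The package bundles a ridge-regression fitter for
  fixture-scale calibration and a neutral occupancy heuristic as the
  default; a production affinity model is explicitly out of scope.
* **Normalization.** The ranges are not fixed by the method description,
  so they are config-exposed: docking score [0, −12] (more negative is
  better) and affinity pAct [2, 12] by default, both clamped. Whether
  normalization should be per-dataset min–max or fixed-range is an open
  question; fixed-range with clamping was chosen because it keeps scores
  comparable across runs and makes outliers safe.
* **Fusion.** CS = α·2Dsim + β·3Dsim + γ·IntDock + δ·IntSim with
  defaults (0.027, 0.324, 0.378, 0.270). `optimizeWeights()` performs
  the exhaustive grid search at step 0.027 (the printed weight
  resolution) over weight sums in [0.95, 1.05] (the printed weights sum
  to 0.999), choosing per combination the CS threshold that maximizes
  F1. Whether the original threshold was fixed or optimized per
  combination is unstated; optimized-per-combination is the default and
  a fixed threshold can be emulated downstream. The confidence gate for
  the fragment library is CS ≥ 0.6; the comparator is config-exposed
  because the method description uses both "0.6 or greater" and
  "> 0.6".

## Exhaustive fragmentation

"Every possible substructure derivable from the disconnection rules" is
formalized as: cut all BRICS-cleavable bonds, take the minimal
fragments, and return one fragment per connected induced subgraph of the
minimal-fragment adjacency graph (equivalently, every connected piece
obtainable by cutting any subset of cleavable bonds). The BRICS link
environments (L1–L16) and their compatibility table are authored as R
predicates over the package's molecule graph; an independent
implementation of the same published rule set is the oracle in the test
suite, which also checks fragment counts against brute-force
connected-subgraph enumeration. Molecules with more than 14 minimal
fragments fall back to subgraphs of ≤ 8 minimal fragments with a
truncation flag (combinatorial safety).

Properties are computed on hydrogen-capped fragments (attachment points
become H) because the fragment-likeness criteria only make sense on real
molecules; whether the original computed them on dummies or hydrogens is
unstated, and the choice shifts MW/HBA only marginally. Ring count is
the cycle-space rank; rotatable bonds are acyclic single bonds between
non-terminal heavy atoms excluding amide C–N. The filter is MW ≤ 300,
HBD ≤ 3, HBA ≤ 6, 1 ≤ NR ≤ 4, NRB ≤ 5, all simultaneously.

## Library, fingerprints and queries

Unique fragment–protein pairs are keyed on (fragment InChIKey, protein
accession); sub-pocket identity is deliberately not part of the key. The
"protein environment" of a fragment is the set of residues with any
heavy atom within 5 Å (config-exposed; the method description never
defines it numerically).

Interaction fingerprints use geometric criteria chosen to match the
published conventions of the common fingerprint libraries: H-bond
donor–acceptor heavy distance ≤ 3.5 Å with D–H···A ≥ 130° when an
explicit hydrogen exists (distance-only otherwise, e.g. protein donors
without modeled hydrogens); π-stacking at ring-centroid distance
≤ 5.5 Å, parallel ≤ 30° or T-shaped 60–90°; hydrophobic ≤ 4.5 Å; ionic
≤ 4.5 Å between opposite formal charges; halogen ≤ 3.5 Å. All are
config-exposed. "Replicating the exact same set of interactions" is read
as strict equality restricted to the reference residues; a superset
(containment) mode is also shipped because the phrasing is ambiguous.

Scaffold hopping requires a candidate fragment to overlap the reference
core above a Gaussian shape-overlap Tanimoto of 0.5 and to offer, for
every reference attachment vector, an attachment point within 1.0 Å and
30°; candidates rank by vectors matched, then shape overlap, then CS.

## Validation machinery

Success is heavy-atom RMSD < 2.0 Å, computed symmetry-aware (minimum
over element- and bond-order-colored graph automorphisms, capped at 10⁴
mappings with fallback to the identity matching plus a flag) after
least-squares Cα superposition of the receptors. Leave-one-out excludes
the query's own entry by default; key-based exclusion is available
because the two conventions differ exactly in the exact-copy scenario
the self-recovery check exploits. Binding sites are single-linkage
clusters of pose centroids cut at 8 Å (the clustering algorithm and
cutoff are unstated in the source protocol; this is our documented
choice).

## The synthetic study system

`makeToyComplex()` builds a rigid, format-valid synthetic receptor: ten
glycines on a 9.5 Å ring (seeded ±0.25 Å jitter), a phenylalanine whose
ring stacks 3.8 Å above the ligand plane, and a serine whose hydroxyl
sits 2.9 Å beyond the para-substituent position — so π-stacking,
H-bond, halogen-bond and hydrophobic detections are all exercised by
construction. The template is toluene; queries are para-substituted
analogs sharing the aromatic core coordinates exactly, making the true
core RMSD zero by construction and the ≥ 6-atom MCS guaranteed.
`toyPipelineConfig()` narrows the normalization ranges (dock [0, −4],
affinity pAct [2, 6]) because the small open shell spans a narrower
energy range than real pockets, and uses 3 conformers and 2 random
starts because the ligands are rigid.

What the toy emulates: the full code path from PDB/SDF input through
template selection, alignment, tethered refinement, scoring,
fragmentation and library queries, with known ground truth. What it does
not emulate: pocket desolvation and induced fit, flexible ligands with
competing binding modes, crystallographic noise, and realistic binding
thermodynamics. Passing the toy checks therefore demonstrates
correctness of the machinery, not prospective accuracy on real
complexes.

`makeScoredDataset()` draws the four metrics uniformly on [0,1],
computes the planted CS, and labels success as (CS + noise) above the
median CS; with zero noise the data are separable by construction and
the planted weights lie on the search grid, so the grid search must
recover them exactly — the acceptance script measures the recovery
cosine and F1.

## Problem sizes

The test suite and acceptance script run at desk scale: 3 toy queries
(≤ 9 candidate poses each), conformer ensembles of 3–5, a 200-row scored
dataset for weight recovery (grid ≈ 3 × 10⁴ combinations), 24 molecules
for the fragmentation oracles, and 100 random perturbations for the
symmetry-RMSD bound. These sizes were chosen so every check runs in
seconds to a couple of minutes while still exercising each branch of the
pipeline.

## Known limitations

* Pose refinement is a local model, not a transferable force field;
  energies are only meaningful for ranking within one system.
* The bundled affinity estimator is a fixture-scale calibration, not a
  trained interaction-feature model.
* Protonation and InChIKey generation depend on the pinned Open Babel
  build; different builds may alter tautomer/charge assignments.
* Aromaticity follows Open Babel's mol2 perception (plus propagation to
  heteroatoms on aromatic bonds); exotic ring systems may be perceived
  differently than by other toolkits.
* The external-structure checks (cross-PDB template similarities,
  large-scale benchmark rates) require network access and third-party
  datasets and are not part of the desk-scale suite.
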