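---
title: "Scoring and pruning protein models by learned residue correctness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and pruning protein models by learned residue correctness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescorrect)
```

## The problem and the model

Automatically built protein models contain localized errors — residues
traced into noise, reversed peptide carbonyls, side chains on the wrong
rotamer — that a crystallographer finds by weighing many weak signals at
once: fit to density, geometry, displacement parameters, clashes.
`rescorrect` formalizes that judgement as supervised regression. Each
residue is a data point; its features are per-residue validation metrics;
its target is a binary correctness label obtained by comparing the model
with a reference structure; the prediction is a continuous correctness
score used for review lists and for automatic pruning.

Regression rather than classification is deliberate: intermediate scores
grade how suspicious a residue is, which is what both a reviewer and a
threshold-based pruner need. The networks are intentionally tiny (one
hidden layer of ten tanh units, linear output) — with 12 or 9 inputs and
hundreds of thousands of potential training residues, capacity, not
regularization, is the binding constraint, and a small network trains in
seconds and is trivially serializable.

### Correctness targets

A residue's main chain is labelled correct (1) iff every main-chain atom
present — N, Cα, Cβ, O, C — lies within 1.0 Å of a *same-named* atom
anywhere in the reference; side chains are labelled the same way over
atoms from the γ position onwards. Name-only equivalence (rather than
requiring the same residue type) tolerates unsequenced or renumbered
chains, which is exactly the state of automatically traced models.
Asparagine, glutamine and histidine side chains fit density equally well
with the terminal χ rotated by 180°, so the flipped conformation is also
accepted, implemented as name-swapped pairwise comparison
(OD1↔ND2, OE1↔NE2, ND1↔CD2 with CE1↔NE2). Aspartate/glutamate flips are
*not* accepted: the rule covers only the three types whose flip is a
genuine density ambiguity. The 1 Å cutoff is a convention, not a fitted
constant; labels near the boundary are necessarily noisy, which the
learner tolerates.

### Features

Twelve main-chain and nine side-chain features are computed per residue
(see the README table). Three design choices matter most:

* **Robust standardization.** Density values (divided by the atomic
  number, so that carbon and sulfur are comparable) and B factors are
  converted to modified Z-scores, M = 0.6745 (x − x̃)/MAD, over
  structure-wide populations kept separate per atom class and per map.
  Median/MAD resists the heavy tails that errors themselves create. When
  MAD = 0 the mean absolute deviation takes over (M = (x − x̃)/1.2533
  meanAD); if that is also zero all scores are 0. A consequence worth
  remembering: scores are *relative to the structure* — deleting bad
  regions shifts everyone else's Z-scores.
* **Error-specific detectors.** The pepflip flag fires when a positive
  difference-map peak above 4.45 rmsd sits where the peptide O or N could
  move under a bond rotation, gated by calibrated windows (peak–C
  0.89–2.75 Å, peak–Cα 1.01–3.71 Å, peak–Cα(next) 1.84–3.87 Å, angle
  peak–C–O > 60.9°; N rule peak–Cα < 2.09 Å, peak–O(prev) < 1.46 Å). The
  windows ship as defaults and can be re-calibrated with
  `calibrate_pepflip()`, which runs Nelder–Mead on −TP + 5·FP. The
  objective is piecewise constant, so the initial simplex is scaled to
  Å-size steps; even so, the optimizer refines reasonable initial
  estimates rather than discovering windows from nothing, and it returns
  the initial parameters (with a warning) when it cannot improve.
  The "difference density Z at the next Cα" feature exists for the same
  reason: a reversed amide often leaves both O and N in density, and the
  clearest symptom is negative difference density one residue along.
* **Resolution as a context feature.** Resolution is constant within a
  structure and carries no per-residue information by itself; it is
  included so the network can reweight other features (e.g. trust rotamer
  priors more at low resolution). Within a single-structure training run
  it is constant and its scaler falls back to unit variance (a warning,
  and a scaled column of zeros).

Missing values (chain termini, absent neighbours, missing χ atoms) are
explicit `NA` throughout feature extraction; imputation with
*training-set medians* happens only in the learning stage, so the
feature tables remain honest.

### Training protocol

Features are imputed, then centred and scaled to unit variance
(population variance; the distinction from sample variance is far below
any tolerance used here but is fixed and documented). Training/test
splits are by *structure*, never by residue, at a 4:1 ratio — residues of
one crystal share the resolution, the map quality and systematic
labelling noise, so residue-level splits would leak. Optimization is Adam
(learning rate 10⁻³, β₁ 0.9, β₂ 0.999, minibatch 200) for at most 200
epochs with L2 penalty α = 10⁻⁴ and squared-error loss; there is no early
stopping, so a run is fully determined by its seed, and the serialized
JSON records the seed together with medians, scaler statistics and all
weights. Test-set coefficient of determination (COD = 1 − SS_res/SS_tot)
is the reporting number; classification metrics use a 0.5 threshold with
scores ≥ 0.5 predicted correct.

### Pruning policy

Four stages, with the main/side score medians computed once over the
input structure and frozen (this avoids order-dependent cascades):

1. chains of at most 20 residues whose mean main-chain score is < 0.2×
   the median main score are deleted, worst mean first;
2. remaining residues with main score < 0.5× median are deleted, worst
   first;
3. side chains with side score < 0.5× the side median are truncated to
   Cβ, worst first;
4. residues left without a surviving peptide-bonded neighbour
   (sequence-adjacent *and* C–N < 2.0 Å, so chain breaks count as
   boundaries) are removed.

Every threshold is a strict "less than": a score exactly at a threshold
survives. Stages 1–3 are capped at 20% of their eligible population
(total residues for 1–2, side-chain-bearing residues for 3; independent
caps). Under the cap, deletion is worst-first; stage 1 stops at the first
chain whose deletion would exceed the residue cap rather than skipping to
a smaller chain — a simpler rule with identical behaviour except in
contrived ties. Chain lengths are measured on the input model. All of
these choices are configurable through `prune_config()`.

## The synthetic test-bed

`build_polypeptide()` places a single chain with ideal bond lengths and
angles; φ/ψ target −57/−47° (helix) or −120/+120° (strand) with 3° seeded
jitter, ω near trans (σ = 1.2°), side chains on the most common library
rotamer, B factors log-normal (meanlog = log 20, sdlog = 0.25).
`degrade()` realizes a chosen fraction of residues as errors in three
modes mirroring real tracing failures: scattered rigid shifts (default
2.5 Å, safely past the 1 Å rule), one contiguous displaced fragment
(chain-into-solvent), and reversed carbonyls implemented as a 180°
rotation of the O torsion — which moves O by ≈ 2.1 Å, leaves the next
residue's truth untouched, and produces exactly the difference-map
signature the pepflip detector targets. Wrong-rotamer side chains (χ₁ +
120°) degrade side-chain truth only. The emitted truth table is always
recomputed by the labeller on the output coordinates — the plan requests
errors, the labeller defines them — and shifts that accidentally land
within 1 Å of reference atoms are re-drawn.

`make_map_pair()` emulates the map pair a refinement program would
produce: the "best" map is a Gaussian-atom map of the *reference* (each
atom a Gaussian of integrated weight Z × occupancy and per-axis variance
B/(8π²) + (0.425 × resolution)², a real-space stand-in giving
resolution-dependent blur without structure factors) plus white noise;
the difference map subtracts the model-calculated map after scaling both
to unit rmsd. Correct residues therefore sit in matching density;
displaced ones generate paired positive/negative difference features.

What this test-bed does **not** emulate: refinement-correlated noise,
solvent contribution, likelihood weighting, crystallographic symmetry,
experimental labelling noise from imperfect references, and the
correct/incorrect class imbalance of real model-building sets. Passing
tests therefore demonstrate that the machinery — features, learning,
policy — behaves as specified, not that the shipped defaults reach any
particular accuracy on real crystallographic data. The Ramachandran
tables and rotamer library are smooth analytic approximations of the
empirical distributions (wrapped-Gaussian mixtures on a 5° grid,
normalized to integrate to 1; per-χ staggered modes with frequencies),
shipped as JSON and pluggable so empirical tables can be dropped in.

## Numerical choices

* Map grids are axis-aligned with uniform spacing; `calc_map` requires
  spacing ≤ resolution/3 (default resolution/4) and truncates each atom's
  Gaussian at 4.5σ (< 0.1% mass loss, verified by the mass-integral
  test). Interpolation is trilinear; peaks are strict 26-neighbourhood
  maxima on nodes, with no sub-voxel refinement — the pepflip windows are
  Å-scale, an order coarser than a voxel.
* The map–model correlation mask radius is 2.5 Å (configurable), chosen
  to cover bonded density at typical working resolutions.
* Overlap volumes use the exact sphere-lens formula with shipped van der
  Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å); pairs within two bonds
  in the covalent graph (including the peptide C–N link) are excluded.
  Ideal geometry still shows sub-Å³ 1–4 contact volumes; genuine clashes
  are several times larger.
* Torsions follow the standard IUPAC sign convention (cross-checked
  against an independent implementation); angles wrap into (−180, 180],
  and the peptide twist is the wrapped distance to the nearer of 0/180°.
* Kabsch superposition enforces determinant +1 and returns the identity
  when the model is already within 0.1 Å mean Cα deviation. There is no
  symmetry or origin search: fixtures live in one frame, and real use
  assumes the model has been symmetry-matched beforehand.
* B-change uses the neighbour's B as denominator and is floored at 0
  ("percentage increase"); neighbours with B = 0 are skipped. Alternate
  conformations keep the highest-occupancy conformer; hydrogens and OXT
  are ignored in both atom classes.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
material sized for a single CPU: 200-residue chains for the end-to-end
pipeline, 15 structures × 80 residues for multi-structure training,
n = 5000 rows for pure feature-table recovery, 500 random score tables
for the pruning cross-check, and 10⁶-point Monte-Carlo for the overlap
oracle. These sizes give stable statistics (AUC, COD, removal rates)
while keeping a full run in minutes; they are choices of the package, and
all scale up by argument.

## Known limitations

* Correctness scores are structure-relative (Z-score features), so they
  are not comparable across structures and drop as a model improves.
* The labelling rule inherits every limitation of the reference model,
  including unmodelled alternate conformations.
* The pepflip windows shipped as defaults were calibrated on large real
  structure sets elsewhere; on synthetic maps they are conservative.
* Networks trained on the synthetic generator are demonstrations; for
  production scoring, train on real model/reference pairs and ship that
  JSON instead.
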