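# rescorrect

Per-residue correctness scoring and automatic pruning for partially built
protein crystal structures.

Automated model-building programs trace polypeptide chains into electron
density quickly, but their output contains errors: short chains built into
solvent, displaced residues, reversed (flipped) peptide carbonyls and
wrong-rotamer side chains. Finding these by eye is the slowest step of
structure solution. `rescorrect` emulates the crystallographer's
decision-making: it combines many per-residue validation signals into a
single learned *correctness score* and uses the scores to prune suspect
parts of a model so that subsequent rebuilding cycles can correct them.

## What it computes

For every residue, 12 main-chain and 9 side-chain features:

| Feature | Main | Side |
|---|---|---|
| real-space map–model correlation (masked, Pearson) | x | x |
| mean / minimum "best"-map density modified Z-score | x | x |
| minimum difference-map density modified Z-score | x | x |
| maximum B-factor modified Z-score | x | x |
| maximum B-factor percentage-increase Z-score | x | x |
| maximum van der Waals overlap volume (Å³) | x | x |
| resolution (Å) | x | x |
| Ramachandran probability score | x | |
| maximum peptide twist, min(\|Δ(ω,0)\|, \|Δ(ω,180)\|) | x | |
| pepflip difference-peak flag (0/1) | x | |
| difference-density Z at the next residue's Cα | x | |
| rotamer score (most common rotamer = 100) | | x |

Density and B-factor values are standardized with the modified Z-score
M<sub>i</sub> = 0.6745 (x<sub>i</sub> − x̃)/MAD computed over
structure-wide populations, separately for main-chain (N, Cα, Cβ, O, C)
and side-chain (γ onwards) atoms. The pepflip detector asks whether a
positive difference-map peak above 4.45 rmsd sits where the peptide O or N
could move under a bond rotation, using calibrated distance/angle windows
(peak–C 0.89–2.75 Å, peak–Cα 1.01–3.71 Å, peak–Cα(next) 1.84–3.87 Å,
peak–C–O angle > 60.9°; N rule: peak–Cα < 2.09 Å, peak–O(prev) < 1.46 Å).

Two small neural networks (one hidden layer of 10 tanh units, linear
output, squared-error loss with α = 10⁻⁴ L2, Adam, ≤ 200 epochs) regress
the features onto binary correctness targets, assigned by comparison with
a reference structure: a residue's main chain is correct iff every
main-chain atom lies within 1 Å of a same-named reference atom (side
chains likewise from γ onwards, with Asn/Gln/His terminal 180° flips
accepted). Predicted scores drive a four-stage pruning policy: delete
chains of ≤ 20 residues whose mean score is < 0.2× the structure median,
then residues < 0.5× median, truncate side chains < 0.5× the side median,
then remove isolated residues — at most 20% per stage, worst first.

A synthetic generator (ideal-geometry polypeptides, seeded degradation
with known truth, Gaussian-atom map pairs) makes the whole pipeline
testable without crystallographic data.

## Worked example

```r
library(rescorrect)

reference <- build_polypeptide(120, conformation = "helix", seed = 4)
deg  <- degrade(reference, perturbation_plan(fraction_incorrect = 0.15, seed = 4))
maps <- make_map_pair(reference, deg$model, resolution = 2.0,
                      noise_sigma = 0.05, seed = 4)
feats <- assemble_features(deg$model, maps$best, maps$diff)
feats[1:3, c("chain", "seq", "res", "main_cc", "rama_score", "max_twist", "pepflip")]
#>   chain seq res   main_cc rama_score max_twist pepflip
#> 1     A   1 LEU 0.6820555         NA        NA       0
#> 2     A   2 TYR 0.3694069         NA        NA       0
#> 3     A   3 ASN 0.7504197         NA 0.1364719       0
```

Residue 2 was one of the planted errors: its map correlation is poor and
the chain break around it leaves the torsion-based features missing
(explicit `NA`, imputed later from training medians). Training a network
on the generator's truth labels and scoring every residue:

```r
pp  <- preprocess_fit(feats[, main_chain_features()])
x   <- preprocess_apply(feats[, main_chain_features()], pp)
net <- train_network(x, deg$truth$main_target, seed = 0, preprocess = pp)
scores <- predict_network(x, net)
round(c(correct = mean(scores[deg$truth$main_target == 1]),
        incorrect = mean(scores[deg$truth$main_target == 0])), 3)
#>   correct incorrect
#>     0.832    -0.286
```

Correct residues score near 1, planted errors near 0 (scores are
unbounded regression outputs, not probabilities). Pruning with these
scores removes the planted errors:

```r
tab <- data.frame(chain = feats$chain, seq = feats$seq, ins = feats$ins,
                  main_score = scores,
                  side_score = ifelse(feats$has_side, 1, NA))
res <- prune(deg$model, tab)
res$report
#> prune_report: 0 chain(s), 19 residue(s), 0 side chain(s), 2 isolated residue(s) deleted
```

File-level wrappers (`cmd_simulate`, `cmd_label`, `cmd_train`,
`cmd_score`, `cmd_prune`) read/write PDB, CCP4 maps, CSV tables and JSON
networks; `inst/cli/rescorrect.R` exposes them as shell subcommands.

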