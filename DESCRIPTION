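Package: rescorrect
Title: Per-Residue Correctness Scoring and Pruning for Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation toolkit for partially built protein crystal
    structures. Computes twelve main-chain and nine side-chain per-residue
    validation features (real-space map-model correlation, robust
    density and B-factor Z-scores, van der Waals overlap volumes,
    Ramachandran and rotamer probabilities, peptide twist and a
    difference-map peptide-flip detector) from a coordinate model and a
    pair of density maps, trains one-hidden-layer neural networks to
    predict binary residue correctness from those features, and applies
    the predicted scores in an automatic median-relative pruning policy
    that deletes suspect chains, residues and side chains. Includes a
    synthetic polypeptide, perturbation and map generator so the whole
    pipeline is testable without crystallographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
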