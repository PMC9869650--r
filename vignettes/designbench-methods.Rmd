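---
title: "Evaluating fixed-backbone sequence design: models, metrics and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating fixed-backbone sequence design: models, metrics and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(designbench)
```

## The evaluation problem

Fixed-backbone sequence design (inverse folding) asks: given the backbone
coordinates of a protein, what amino-acid sequence would fold into it? Design
methods emit, for each position, either a single amino acid or a probability
distribution over the 20 canonical residues. Evaluating them naively by
sequence recovery (the fraction of positions where the argmax matches the
native residue) is misleading for two reasons this package is built around:

1. **Amino-acid composition is heavily imbalanced.** A model that overpredicts
   leucine or alanine gains accuracy without learning anything about less
   common residues. Macro-recall — the unweighted mean of per-class recalls —
   is insensitive to composition and is the headline imbalance-resistant
   score here.
2. **Performance varies systematically with structure class.** Methods that
   look strong on a helix-rich evaluation set may fail on mainly-beta folds.
   Every group metric is therefore stratified: per chain, per
   secondary-structure state and per CATH fold class and architecture, so a
   balanced comparison across fold classes is always available.

The package evaluates prediction matrices against backbone structures and a
CATH-annotated dataset map; it does not bundle an evaluation set of real
structures (only the static fold-class composition table of the curated
595-chain benchmark ships, for bookkeeping), and it does not run any design
method.

## Metric definitions

With confusion matrix $C_{ab}$ (rows: true residue $a$, columns: argmax
prediction $b$; argmax ties broken by alphabet order for determinism), the
per-class metrics are:

* recall$(a) = C_{aa} / \sum_b C_{ab}$, precision$(a) = C_{aa} / \sum_b C_{ba}$,
  F1 their harmonic mean;
* AUC$(a)$: one-vs-rest ROC area using the predicted probability of $a$ as the
  score, in the Mann–Whitney midrank form so probability ties contribute 1/2.
  AUC pools residues within the evaluation unit rather than averaging over
  chains;
* entropy$(a) = -\sum_b q(b\mid a)\log_2 q(b\mid a)$ in bits, where
  $q(\cdot\mid a)$ is row $a$ of the confusion matrix normalized. We compute
  entropy from the discrete argmax confusion rather than from averaged
  probability vectors: it is then well defined for both probabilistic and
  one-hot inputs, and directly answers "what does the model predict when the
  truth is $a$". This is an isolated choice behind `perClassMetrics()`;
* bias$(a) = (n_\mathrm{pred}(a) - n_\mathrm{true}(a)) / n_\mathrm{true}(a)$:
  0 for a calibrated class, $-1$ for a class never predicted, positive for
  overprediction. The definition is dimensionless and signed so that
  "negative bias towards common residues" reads directly off the bar chart.

Group metrics (global and per stratum): accuracy; macro-precision and
macro-recall, where classes absent from the stratum's truth (and, for
precision, classes never predicted) are skipped rather than imputed 0 — a
chain simply lacking tryptophans should not be penalized for composition;
similarity, which relaxes accuracy to count substitutions with a strictly
positive BLOSUM62 log-odds score as correct (positive log-odds means the
substitution occurs more often in nature than chance, so score-0 pairs do
*not* count); and top-3 accuracy, with ties again broken by alphabet order.
Any metric with a zero denominator is reported as absent (`NA`), never as 0.

Chain-level accuracy is also correlated (Pearson) against crystal resolution;
the correlation is reported as absent when fewer than 3 chains carry a
resolution or either variable is constant.

## Secondary structure

Assignment follows backbone hydrogen bonding. Because crystal backbones lack
hydrogens, the amide H is reconstructed 1.01 Å from N along the normalized sum
of the unit vectors $N - C_{prev}$ and $N - CA$ — an approximation of the
convention used by Kabsch–Sander-style assigners (prolines and chain-initial
residues donate nothing). The bond energy is the standard electrostatic model

$$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\ \mathrm{kcal/mol},$$

with a bond recorded when $E < -0.5$ kcal/mol at sequence separation ≥ 2, and
distances below 0.5 Å treated as a clash error. Helices are residues
$i..i{+}3$ wherever $CO(i{-}1){\to}NH(i{+}3{+}1)$ and $CO(i){\to}NH(i{+}4)$
turns coexist; strands are residues in parallel or antiparallel bridge
patterns (separation ≥ 3). A residue matched by both patterns is helix:
fixed precedence keeps the assignment deterministic. The built-in assigner
emits only H/E/C — no 3₁₀/π distinction, β-bulges or bends; the finer 8-state
codes enter only via DSSP file import, reduced H,G,I→H; E,B→E; T,S,C→C. On
the packaged ideal-geometry fixtures the two routes agree on ≥ 90% of complete
residues, the documented tolerance for this simplification. Metrics stratify
on the 3-state alphabet by default; 8-state labels are kept when a DSSP file
provides them.

## Geometry

Torsions use the standard IUPAC signed dihedral in $(-180°, 180°]$. The
Ramachandran comparison bins (φ, ψ) on a fixed 10° grid (36×36), separately
for the positions where an amino acid is true and where it is predicted —
contrasting the two diagnoses *where in conformation space* a method
overpredicts a residue type. Positions missing either torsion (termini, chain
breaks, missing atoms) are excluded from both histograms, so each histogram's
counts sum exactly to its contributing positions.

## What the synthetic fixtures emulate

All tests run on generated data, so the planted truth is known analytically:

* `buildChainFromTorsions()` grows backbones by natural extension with ideal
  bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ω fixed trans),
  which makes the φ/ψ round-trip exact to numerical precision;
* `makeIdealHelix()` uses (−57°, −47°); `makeAntiparallelSheet()` lays two
  flat fully-extended strands antiparallel in a common plane at 4.8 Å
  spacing. The registry shift along the strand axis is derived from the
  construction: the second strand is the first rotated 180° about the
  in-plane carbonyl normal and translated so residue $k$ faces residue
  $n{+}1{-}k$, which places facing amides and carbonyls within hydrogen-bond
  range and yields a clean antiparallel ladder (edge residues stay coil);
* `makePredictions()` plants predictor behaviour: `perfect`, `uniform`,
  `constant`, `biased` (with probability $s$ emit the bias letter, else the
  truth, so expected accuracy is $(1-s) + s f_x$ — a probabilistic mixture,
  since a deterministic convex combination would have a deterministic argmax
  and nothing to test at binomial tolerance), and `softmax_noise`
  (temperature-scaled Gaussian logits with a +2 shift on the true class);
* `makeToyBenchmark()` writes 8 chains spanning the four CATH fold classes
  with seeded sequences and resolutions, the dataset map, synthetic
  DSSP-style files and planted composition sidecars. Two runs with one seed
  are byte-identical.

What the fixtures deliberately do **not** emulate: crystallographic noise,
missing density, side chains, alternate conformations beyond simple altloc
records, realistic amino-acid composition, or sequence–structure correlation.
Passing tests therefore demonstrate the correctness of the bookkeeping,
metrics and geometry, not that any design method performs well on real
proteins.

## Input conventions and degenerate cases

* Prediction CSV: header `chain_key,position,A,...,Y`; rows per chain
  contiguous and in structure order; alignment to the structure is by order
  (what a design method naturally emits), with a hard error when the row
  count differs from the chain's canonicalized residues. Row sums in
  $[0.99, 1.01]$ are renormalized (absorbing float truncation); anything
  further off is an error, as are negative entries — silent repair would
  hide real bugs.
* Dataset map: `chain_key architecture_code structure_path`, `#` comments;
  fold class from the leading CATH class digit (1 → mainly-alpha, 2 →
  mainly-beta, 3 → alpha-beta, else special).
* PDB reading: first model only; altloc resolved to highest occupancy (ties:
  first encountered); waters and non-canonicalizable HETATM records dropped;
  MSE and friends map to their parent residue via a shipped substitution
  table. Residues that still fail canonicalization are kept in the chain but
  excluded from all metrics and reported in per-chain exclusion counts — no
  ground truth, nothing to score.
* Model comparison demands an identical scored residue set across models;
  a silent intersection would compare apples to oranges, so it is an error.

## Problem sizes

The test-suite and acceptance computations use desk-scale problem sizes
chosen to exercise every code path while keeping the suite fast: toy
benchmarks of 8 chains (~150 residues), oracle checks on 20 random instances
of 50–500 residues, and planted-predictor recovery at n = 2000 within 3
binomial sigma. These sizes are the package's own test design; the tool
itself streams any number of chains.

## Example

```{r example, eval=FALSE}
dir <- tempfile()
info <- makeToyBenchmark(dir, seed = 7)
dmap <- readDatasetMap(file.path(dir, "dataset_map.txt"))
truth <- unlist(info$truth, use.names = FALSE)
keys <- rep(names(info$truth), lengths(info$truth))

noisy <- makePredictions(truth, "softmax_noise", chainKeys = keys,
                         modelName = "noisy", seed = 1)
report <- buildModelReport(noisy, dmap, baseDir = dir)
report
strataMetrics(report, "fold_class")
writeReport(report, file.path(dir, "out"))
```

## Known limitations

The built-in assigner is a deliberate simplification of full
Kabsch–Sander assignment (no π/3₁₀ helices, bends or β-bulges); mmCIF input,
NMR multi-model handling beyond the first model, and network CATH lookups are
out of scope (architecture codes come from the dataset map). Statistical
significance tests and bootstrap intervals between models are future work.
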