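---
title: "Distilling mutational landscapes from protein language model embeddings"
author: "mutscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling mutational landscapes from protein language model embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

## The problem

Deep mutational scans (DMS) measure a phenotype for thousands of amino-acid
substitutions of one protein, but experiments will never cover whole
proteomes. Evolutionary methods such as GEMME predict substitution effects
from multiple sequence alignments (MSAs) with high accuracy, at the price of
building an alignment per protein. Protein language models (pLMs) offer a
shortcut: their per-residue embeddings already encode rich evolutionary
context, and the usual masked-token log-odds scoring of variants is the slow
part, not the embedding itself.

`mutscape` implements the expert-guided ("student–teacher") shortcut: a
shallow regression network maps each residue's pLM embedding (a vector of
width $d$; $d = 2560$ for the reference ESM-2-style backbone) directly to the
full 20-dimensional vector of substitution scores for that position. The
student is trained once, by masked mean squared error, against teacher
matrices of evolutionary scores; at inference time no alignment, no MSA and
no log-odds computation is needed — one forward pass per residue yields the
complete $L \times 20$ mutational landscape.

## Data model

* A **Landscape** is an $L \times 20$ score matrix plus a logical mask.
  Columns follow the fixed alphabetical amino-acid order
  `ACDEFGHIKLMNPQRSTVWY`; every file reader remaps to this order so that a
  column index always means the same substitution. Wild-type
  self-substitution cells are always masked: the teacher defines no score
  for them. Teacher scores live in $[-10, 2]$, lower = more deleterious.
* A **MultiVariant** is one or more single substitutions with pairwise
  distinct 1-based positions, written `X<pos>Y` (`G76A`), joined by `:` for
  multi-mutants. Positions are 1-based in all notation and file columns;
  matrix indexing is 0-shifted only inside the package, with conversion at
  the parse/format boundary.
* Multi-mutants are scored **additively** over their single-substitution
  scores. The landscape contains only single substitutions, so additivity is
  the minimal epistasis-free model; no interaction model is attempted.
* **Normalization** to the $[0, 1]$ impact scale is the linear,
  order-reversing rescale $(s_{\max} - s) / (s_{\max} - s_{\min})$ with
  clipping, defaults $(-10, 2)$ from the teacher range, both bounds
  configurable. A raw score of $2$ maps to impact $0$, $-10$ to $1$, $-4$ to
  $0.5$. Normalizing an already-normalized landscape is rejected via the
  role tag.

## Student architectures and training

Four architectures are implemented, all ending in a linear (no activation)
20-unit output layer:

| name | structure | default sizes |
|------|-----------|---------------|
| `linreg` | affine map | — |
| `fnn1`   | one hidden layer | 256 units (the reference; 660,756 parameters at $d = 2560$) |
| `fnn2`   | two hidden layers | 256, 64 |
| `cnn`    | 1-D convolution over the residue axis, then two dense layers | 256 channels, kernel 7; 256, 64 |

Hidden layers use LeakyReLU (slope 0.01). The convolution is implemented as
a dense layer on im2col features (each residue's window of $k$ neighbouring
embedding rows, zero-padded at the termini), which makes every architecture
a dense stack served by one backpropagation path. An ensemble predictor
averages the raw landscapes of two separately trained networks cell-wise.

The loss is the **masked MSE**: cells undefined in the teacher (NA entries
plus self-substitutions) contribute to neither numerator nor denominator.
Training uses minibatch Adam (default learning rate $10^{-4}$, batch 1024
residues, at most 200 epochs) with early stopping on validation loss
(patience 10) and best-weights restoration. Two optional refinements,
both off by default:

* **step learning-rate decay** (halve every `lrDecayEvery` epochs) — a
  constant Adam step leaves a stationary "noise ball" whose radius scales
  with the learning rate; decaying lets late epochs refine instead of
  oscillate;
* **decoupled weight decay** (AdamW-style) on weight matrices — with noisy
  teacher scores, a higher-capacity student will otherwise spend capacity
  reproducing the noise realization (its training loss can drop below the
  noise floor), which costs held-out accuracy.

All randomness (initialization, shuffling, splits, generators) is seeded and
run single-threaded, so runs are bit-reproducible.

At the default learning rate of $10^{-4}$, an Adam step moves each
weight by at most about the learning rate, so small desk-scale corpora need
either many epochs or a larger step; the convergence examples in the test
suite use 0.01–0.05. All settings are exposed through `trainConfig()`.

## Dataset curation

Curation follows a fixed, order-stable pipeline; each protein is removed by
the first filter that matches, so the report counts always sum to the input
count:

1. **length filter** — keep $25 \le L \le 1024$ (bounds inclusive);
2. **canonical screen** — drop sequences containing letters outside the
   20-letter alphabet (X, U, B, Z, `*`);
3. **redundancy vs the test set** — remove any training sequence whose
   estimated identity to a test sequence reaches the threshold (default
   0.8), preventing leakage;
4. **self-redundancy** — greedy clustering of the survivors (longest-first
   seeds, ties by id) keeping one representative per cluster.

The default identity estimate is deliberately lightweight: exact match or
containment counts as identity 1, otherwise the Jaccard similarity of 6-mer
sets. This is an alignment-free stand-in for a proper clustering tool; a
precomputed cluster assignment (e.g. an MMseqs2 run) can be injected as a
two-column table and then drives step 4 exactly. The train/validation split
is per-protein (no protein contributes residues to both sides), random with
a seed, 80/20 by default.

Teacher landscapes derived from few homologous sequences can be flagged as
low-confidence via an id list; they are kept for training but carry a flag
so downstream code can exclude them from validation metrics.

## Evaluation statistics

* **Spearman** correlations use fractional (tie-averaged) ranks throughout.
* Per-assay evaluation scores every variant additively on the landscape;
  entries touching an undefined cell are dropped and counted, never
  imputed. Because raw landscapes are more negative for more deleterious
  variants, an assay where the phenotype decreases with damage correlates
  positively with raw scores; no automatic sign-fixing is done — the
  evaluation workflow exposes an explicit flip flag instead, since silent
  orientation guessing can hide bugs.
* Grouped aggregates report the unweighted mean of per-assay correlations
  with a $\pm 1.96 \cdot \mathrm{SE}$ half-width (sample standard
  deviation, $n-1$), the normal-approximation 95% confidence interval;
  groups of size one report an undefined half-width rather than a fake one.
* The **phenotype-balanced mean** averages the per-phenotype mean
  correlations so that each phenotype class (Activity, Binding, Expression,
  Fitness, Stability) counts once regardless of how many assays it
  contributes.
* Predictor comparisons use a **one-tailed paired t-test** on per-assay
  correlation differences, upper tail of $t(n-1)$, raw p-values with no
  multiplicity correction. Two edge cases are distinguished: if the two
  predictors agree exactly on every assay the statistic is 0 and $p = 0.5$;
  constant non-zero differences leave the statistic undefined and raise an
  error.
* Mutation-depth stratification partitions an assay by the number of
  simultaneous substitutions and reports per-depth correlations alongside
  the pooled one (the pooled-vs-per-depth choice is ambiguous for
  multi-mutant assays, so both are always available).
* Residue **sensitivity ranks** average each row's defined scores and
  rank residues (rank 1 = most sensitive; direction from the landscape
  role, explicit for experimental data). Two rankings are compared
  per-residue with agree/neither/disagree labels at rank-difference
  thresholds below 5 and above 15.

## The synthetic corpus and what it shows

Every module is testable offline against a generator with planted ground
truth. A synthetic corpus consists of uniform-random canonical sequences,
i.i.d. standard normal embeddings ($d = 64$ by default for test speed; the
reference $d = 2560$ is exercised in shape and parameter-count tests), and
teacher landscapes produced by a planted affine map
$W^\top e + b$ with $W \sim N(0, (1.2/\sqrt{d})^2)$ and $b = -4$: the affine
output is roughly $N(-4, 1.2)$, centred in the teacher range and about five
standard deviations from both bounds, so clipping is negligible and a
noiseless corpus is genuinely realizable by the linear student. Gaussian
score noise, when requested, is added before clipping so the teacher range
invariant always holds.

The optional **mild nonlinearity** is a smooth bounded squashing of the
affine output: each column passes through a tanh centred at $-4$ with
half-range 6 and a per-column steepness (from 0.5 to 2 across the 20
columns — steep columns saturate like low-resolution evolutionary
landscapes, shallow ones stay nearly affine), and each landscape column is
then a 0.7/0.3 convex blend of its own squashed index and its neighbour's.
The blend matters: an elementwise monotone squash of a single affine index
is almost invisible to a rank metric, because the best linear fit of
$g(w^\top e)$ for Gaussian $e$ is itself nearly proportional to
$w^\top e$ — a monotone transform, hence rank-equivalent. Blending two
squashed indices makes no column a monotone function of any single affine
direction, so a linear student pays a genuine rank penalty and the hidden
layer has something measurable to gain.

The headline self-check is the **distillation recovery experiment**
(`recoveryExperiment()`): generate 200 proteins with $L \in [30, 100]$ and
$d = 64$, split 80/20 by protein, train students on the on-disk (possibly
noisy) teacher matrices, and score each student by its mean per-protein
Spearman correlation against the *clean* planted teacher map on held-out
proteins. Scoring against the clean map rather than the noisy files is
deliberate: recovery means learning the mapping, not reproducing one noise
realization. With a noiseless affine teacher the linear student recovers
the planted mapping almost perfectly (mean held-out Spearman above 0.99);
with teacher noise at half the teacher score standard deviation plus the
mild nonlinearity, the one-hidden-layer student overtakes the linear one —
provided both are regularized (the comparison uses learning rate 0.01,
batches of 512 residues, halving every 40 epochs, weight decay 1; without
decay the 21k-parameter network fits the noise instead).

What passing these tests does **not** show: synthetic embeddings are
isotropic Gaussians with no sequence structure, real pLM embeddings are
anisotropic and locally correlated along the chain; the planted teacher has
no epistasis, position coupling or alignment-depth artefacts; synthetic
assays are monotone transforms of landscape scores plus Gaussian noise,
while real DMS assays have floor/ceiling effects, bimodality and
batch structure. The synthetic results validate the machinery (shapes,
masking, optimization, statistics), not biological accuracy.

## Numerical and interface choices

* Teacher matrix files: whitespace-separated text, position-header line,
  then 20 rows each led by an amino-acid letter (any order,
  case-insensitive, quotes tolerated), `NA` for undefined cells; a
  transpose flag accepts the $L \times 20$ orientation. The strict range
  check $[-10, 2]$ is on by default; disabling it clips marginally
  exceeding exports into the range instead of failing.
* The embedding store is a directory with one plain-text matrix per protein
  and a YAML manifest carrying the pLM tag and width; values round-trip at
  full double precision. One store holds embeddings of exactly one pLM —
  mixing widths or backbones in a store is refused.
* Prediction CSVs order rows position-major, alphabet-minor, so re-runs
  diff cleanly. Checkpoints store the full architecture description next to
  the weights and are verified for shape consistency on load; restored
  models predict bit-identically.
* DMS tables follow the public ProteinGym-style column convention
  (`mutant`, `DMS_score`), both names configurable; assay metadata
  (phenotype from the closed five-label vocabulary, taxon) travels in a
  sidecar CSV.
* The command-line workflows (`generate`, `train`, `predict`, `eval`) are
  thin wrappers over exported functions, log to stderr, write results only
  to files, echo their effective configuration as YAML next to every
  output, and return 0/1/2 exit codes (success / usage or config error /
  data error).

## Problem sizes

The test suite runs on corpora of 1–12 proteins ($L \le 50$, $d = 16$–24)
except for the recovery experiment, which uses the 200-protein corpus
described above (about 13,000 residues); the full suite and the recovery
script are sized for a single CPU. The reference $d = 2560$ architecture is
instantiated for shape and parameter-accounting checks only.

## Known limitations

* No bundled pLM: embeddings are consumed precomputed (the store format is
  the interface; a different backbone changes only `d` and the tag).
* No MSA generation and no execution of the evolutionary teacher; teacher
  matrices are inputs.
* Redundancy reduction's k-mer identity estimate is coarse below ~80%
  identity; for publication-grade curation inject external cluster
  assignments.
* Additive multi-mutant scoring ignores epistasis by design.
* The normalization is a linear rescale; percentile- or calibration-based
  alternatives would need the upstream method's official definition.
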