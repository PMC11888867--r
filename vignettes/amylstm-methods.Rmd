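---
title: "Methods: sequence-based amyloid classification with an attention-pooled Bi-LSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based amyloid classification with an attention-pooled Bi-LSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amyloid-forming proteins aggregate into insoluble, β-sheet-rich fibrils and
are central to several neurodegenerative diseases, most prominently
Alzheimer's. Laboratory identification (histochemical dyes, LC-MS/MS) is
accurate but slow and expensive, which makes *in silico* screening from the
primary sequence attractive. `amylstm` implements a sequence-only binary
classifier — amyloid (positive) versus non-amyloid (negative) — built around
a bidirectional long short-term memory network with attention pooling, plus
the classical descriptor-based baselines such a model is normally compared
against, and a seeded synthetic-sequence generator so the entire pipeline is
testable without any external dataset.

## The model

Sequences over the 20 canonical residues are mapped to integer tokens from a
21-letter vocabulary; the 21st token is a combined pad/unknown symbol at
index 0. The vocabulary size is deliberately 21: a single extra symbol
serves both for batch padding and for the rare non-canonical residue codes
(B, J, O, U, Z, X, `*`), whose embedding row is pinned at zero and never
trained. Tokens pass through an embedding of dimension 100, then a
bidirectional recurrent encoder with 64 hidden units per direction, so every
position carries a 128-dimensional hidden state. The LSTM cell follows the
standard gate equations

$$f_t = \sigma(W_f[h_{t-1}, x_t] + b_f), \quad
  i_t = \sigma(W_i[h_{t-1}, x_t] + b_i), \quad
  o_t = \sigma(W_o[h_{t-1}, x_t] + b_o),$$
$$\tilde{c}_t = \tanh(W_c[h_{t-1}, x_t] + b_c), \quad
  c_t = f_t \odot c_{t-1} + i_t \odot \tilde{c}_t, \quad
  h_t = o_t \odot \tanh(c_t),$$

implemented twice in the package: once as a literal per-gate scalar
reference cell (`reference_lstm_step()`), and once as the vectorized batched
cell the training loop uses. The two are checked against each other in the
test suite; the full backward pass is additionally verified coordinate-wise
against central finite differences for all three cell types, with and
without attention.

Attention pooling scores each position through a learned tanh transform
against a context vector,

$$u_k = \tanh(W_k h_k + b_k), \qquad
  \alpha_k = \frac{\exp(u_k^\top u_s)}{\sum_j \exp(u_j^\top u_s)}, \qquad
  V = \sum_k \alpha_k h_k,$$

and the pooled 1×128 vector $V$ feeds a fully connected layer (width 64),
1-D batch normalization, ReLU, and a final fully connected layer with a
sigmoid output. GRU and plain RNN cells, and final-state pooling instead of
attention, are available as ablation variants (`deep_variant_configs()`).

### Design choices where the architecture was open

* **Hidden width.** The pooled attention output is 1×128; with a
  bidirectional encoder this fixes 64 units per direction, which is the
  default.
* **Masking.** Attention scores at padded positions are set to $-\infty$
  before the softmax, and the recurrence carries the previous state through
  padded steps unchanged. Together with the zero pad embedding this makes
  predictions *exactly* invariant to padding length — asserted bitwise in
  the tests — and means final-state pooling reads the state at the true
  sequence end.
* **Attention scoring width.** $u_k$ and $u_s$ share the 128-dimensional
  hidden width, since the score is the inner product $u_k^\top u_s$.
* **No dropout** by default: regularization beyond early stopping is not
  part of the training protocol.
* **Batch normalization needs batch statistics**, so training requires
  minibatches of at least 2; a trailing singleton minibatch is merged into
  its predecessor. Evaluation always uses running statistics, so inference
  on a single sequence is well defined.

## Training and evaluation protocol

Training minimizes mean binary cross-entropy with Adam at learning rate
0.001 for up to 40 epochs (defaults of `train_config()`), shuffling with a
seeded stream, and returns the weights of the epoch with minimum validation
loss. We select that epoch rather than hard-coding any particular one:
convergence epoch is an observation about one run, not a rule. Divergence
(non-finite loss) raises an error naming the epoch.

Data are partitioned by `stratified_split()` with fixed per-class counts:
for the canonical benchmark totals of 165 positives and 382 negatives the
partition is exactly 117/15/33 and 276/29/77 (train/validation/test, totals
393/44/110); other totals are apportioned with the same per-class fractions
by largest remainder, ties to train. The validation set is carved from the
training pool within the same seeded stream.

`evaluate()` reports AUROC as the primary, threshold-free metric, computed
by the Mann–Whitney rank-sum formulation with midranks for ties, plus
balanced accuracy, the Matthews correlation coefficient and F1 at the
default threshold of 0.5 (predicted positive when the probability is at
least 0.5). MCC is defined as 0 whenever a denominator factor vanishes, the
standard convention for degenerate one-class predictions. AUROC is invariant
under strictly monotone transforms of the scores, which the suite checks,
and every metric is verified against brute-force formulas on randomized
confusion matrices.

`run_trials()` repeats training over `n` seeded trials (trial *t* uses base
seed + *t* for initialization and shuffling, with the split held fixed) and
reports per-metric means and standard deviations, mirroring the usual
10-trial robustness protocol.

## Classical baselines

Five descriptor families are implemented against independent brute-force
oracles in the tests:

* **AAC** (20): relative residue frequencies.
* **APAAC** (20 + 2λ): AAC plus hydrophobicity/hydrophilicity
  lag-correlation factors; frequencies and correlation block share the
  normalizer $1 + w\sum\tau$, so λ = 0 reduces exactly to AAC. Defaults
  λ = 4, w = 0.05 — a small λ keeps the length > λ precondition satisfiable
  for short sequences. Property scales are standardized to zero mean and
  unit population variance over the 20 residues.
* **CTDC** (39) and **CTDD** (195): composition and distribution of 3-group
  partitions under 13 physicochemical attributes (seven hydrophobicity
  scales, van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility), the partitions in common use in
  protein-feature toolkits. CTDD reports the percent position of the first,
  25%, 50%, 75% and 100% occurrences, 0 for absent groups.
* **DDE** (400): the deviation of observed dipeptide fractions from
  codon-usage-derived expectations, standardized by
  $\sqrt{T_m(1-T_m)/(N-1)}$, with codon counts over the 61 sense codons of
  the standard genetic code.

Unknown tokens carry no physicochemical assignment and are excluded from
all counts and normalizers. The baseline harness crosses these five
descriptors with k-NN, logistic regression, random forest, SVM (RBF;
decision values as ranking scores, which are monotone in the class
probability) and gradient boosting — 25 models, each with a small
hyperparameter grid (k ∈ {3,5,7,9}; trees ∈ {100,500}; C ∈ {0.1,1,10};
boosting depth ∈ {3,6}) resolved by validation AUROC with first-in-grid
tie-breaking. Standard fitters are used throughout (`class::knn`,
`stats::glm`, `ranger`, `e1071::svm`, `xgboost`); the harness asserts that
every row is scored on the identical test membership and annotates
per-model failures without aborting the grid.

## The synthetic generator

`generate_sequences()` emulates the benchmark's shape at reduced size: by
default 150 positives and 380 negatives (the benchmark's roughly 1:2.3
class imbalance), lengths uniform on 30–200, a uniform background over the
20 residues, and a planted heptamer motif "QNNQQNY" — a polar-zipper-like
segment of the kind associated with aggregation-prone regions — inserted at
a uniform random position in each positive. Two dials control signal:
`motif_prob` (the fraction of positives carrying the motif) and
`composition_shift` (a log-odds tilt of the positive background toward
hydrophobic residues, which is what compositional descriptors like AAC can
detect). The generator is fully seeded and byte-reproducible.

What it does *not* emulate: real amyloid determinants are structural,
degenerate and context-dependent, not a single exact substring; real
sequence backgrounds are far from i.i.d. uniform; and homology structure
between train and test partitions is absent. Passing the planted-signal
tests therefore demonstrates that the architecture, training loop and
evaluation machinery can discover a position-independent local signal — it
does not certify real-data accuracy, which depends on the curated benchmark
dataset.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script train at sizes chosen to exercise
the full pipeline while staying quick on a single CPU: the headline
planted-signal run uses the full 100-dimensional embedding / 64-unit
architecture on the default 150/380 dataset for 8 epochs (a strong planted
signal converges in a handful of epochs; the selected epoch is reported
alongside the metrics), while the null and motif-strength-sweep runs use a
reduced 16/12-unit model. Other fixed choices: sequences longer than
`max_len` (default 1000) keep their N-terminal prefix; BCE probabilities
are clamped to $[10^{-7}, 1-10^{-7}]$; batch-norm uses ε = 1e-5 and
momentum 0.1; weights initialize uniformly in $\pm 1/\sqrt{d}$ per layer
under the run's seed.

## Limitations

The implementation is plain R, vectorized over minibatches; it is intended
for datasets of hundreds to a few thousand sequences, not proteome-scale
screening. Only sequence information is used — no structure, no
evolutionary profiles (the descriptor set deliberately excludes PSSM-type
features). The attention weights exported by `predict_attention()` are a
pooling mechanism, not a calibrated interpretability method; they indicate
where the model looked, not why.
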