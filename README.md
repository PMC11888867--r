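# amylstm

Sequence-based identification of amyloid-forming proteins with an
attention-pooled bidirectional LSTM, implemented from first principles in R.

Amyloid proteins aggregate into insoluble β-sheet-rich fibrils implicated in
neurodegenerative disease (Alzheimer's Aβ plaques being the canonical
example). Wet-lab identification is accurate but slow and expensive, so
sequence-only *in silico* screening is a standard first pass. `amylstm` is
for computational biologists who want a self-contained, fully inspectable
implementation of the recurrent-attention approach to this problem: every
layer — embedding, LSTM/GRU/RNN cells, masked attention pooling, the
batch-normalised head, Adam and backpropagation — is written in R and
verified against independent oracles and finite-difference gradient checks,
rather than wrapped from a deep-learning framework.

## The model

Sequences over the 20 canonical residues (vocabulary 21 with a combined
pad/unknown token) are embedded in 100 dimensions and encoded by a
bidirectional LSTM with 64 hidden units per direction:

    f_t = σ(W_f [h_{t−1}, x_t] + b_f)        (forget gate)
    i_t = σ(W_i [h_{t−1}, x_t] + b_i)        (input gate)
    o_t = σ(W_o [h_{t−1}, x_t] + b_o)        (output gate)
    c̃_t = tanh(W_c [h_{t−1}, x_t] + b_c)     (candidate cell)
    c_t = f_t ⊙ c_{t−1} + i_t ⊙ c̃_t
    h_t = o_t ⊙ tanh(c_t)

The per-position hidden states h_k (1 × 128 after concatenating directions)
are pooled by attention,

    u_k = tanh(W_k h_k + b_k),   α_k = softmax_k(u_kᵀ u_s),   V = Σ_k α_k h_k,

and V feeds FC(128→64) → BatchNorm1D → ReLU → FC(64→1) → sigmoid. Around the
network the package provides the complete benchmarking protocol: stratified
splitting with the canonical 393/44/110 partition arithmetic, Adam/BCE
training with minimum-validation-loss epoch selection, rank-based AUROC plus
balanced accuracy / MCC / F1 at threshold 0.5, a seeded multi-trial
robustness runner, the 25-model classical harness (k-NN, logistic
regression, random forest, SVM, gradient boosting × AAC, APAAC, CTDC, CTDD,
DDE descriptors), RNN/GRU ± attention ablations, and a synthetic generator
that plants a configurable amyloid-like motif so everything is testable
without external data.

## Worked example

Train on a seeded synthetic dataset with a planted polar-zipper motif
(QNNQQNY) in the positive class, evaluate on the held-out test partition,
and inspect where the attention looked:

```r
library(amylstm)

data  <- generate_sequences(synth_config(n_pos = 80, n_neg = 100,
                                         length_range = c(30, 80), seed = 42))
split <- stratified_split(data, seed = 42)

fit <- train(partition(split, "train"), partition(split, "val"),
             model_config(embed_dim = 24L, hidden_per_direction = 16L,
                          fc_hidden = 8L),
             train_config(max_epochs = 20, seed = 42))
fit
#> <amyl_model> bi-lstm + attention: vocab 21, embed 24, hidden 16/dir (pooled 32), fc 8
#> trained 20 epochs, best validation loss 0.2429 at epoch 20

evaluate(fit, partition(split, "test"))
#> # A tibble: 1 × 9
#>   auroc balanced_accuracy   mcc    f1 threshold    tp    fp    fn    tn
#>   <dbl>             <dbl> <dbl> <dbl>     <dbl> <int> <int> <int> <int>
#> 1     1                 1     1     1       0.5    16     0     0    20

predict_attention(fit, head(partition(split, "test"), 1)) |>
  dplyr::slice_max(alpha, n = 3)
#> # A tibble: 3 × 4
#>   id      position residue  alpha
#>   <chr>      <int> <chr>    <dbl>
#> 1 pos_009       49 N       0.0455
#> 2 pos_009       52 N       0.0408
#> 3 pos_009       50 Q       0.0350
```

The model separates the classes perfectly on this strongly separable
fixture (AUROC = 1 with a clean confusion matrix at threshold 0.5), and the
three highest attention weights in the first test sequence sit on residues
of the planted Q/N motif — the pooling found the signal the generator hid.
`autoplot(fit)` draws the loss history, `tidy()`/`glance()` return tabular
summaries, and `run_trials()` repeats the whole protocol across seeds.

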