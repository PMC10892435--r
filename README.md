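# vqcpc — strings of motion from wearable accelerometer data

`vqcpc` turns windows of wrist-worn triaxial accelerometer data into
sequences of discrete *motion symbols* and classifies human activities from
those symbol strings. It is aimed at researchers in human activity
recognition (HAR) and digital health who want compact, interpretable,
token-based representations of movement rather than continuous embeddings —
for classification, summarization, or downstream NLP-style modelling.

## The model

The core is vector-quantized contrastive predictive coding (VQ-CPC):

- **Encoder** `f : X -> Z`. A strided 1-D convolutional network with blocks
  of (32, 64, 128, 256) channels, kernels (4, 1, 1, 1) and strides
  (2, 1, 1, 1), each followed by ReLU and dropout (p = 0.2). Convolutions
  are unpadded, so a 100-sample window (2 s at 50 Hz) yields 49 latent
  *z*-vectors — an output frequency of 24.5 Hz — and each symbol covers a
  receptive field of 4 samples (0.08 s).
- **Quantizer** `q : Z -> Ẑ` (grouped online K-means). Each z-vector is
  split into G = 2 groups of d/G dimensions; per group the nearest of
  V = 100 codebook rows under squared Euclidean distance replaces the
  slice, `i = argmin_j ||z - e_j||²`. The straight-through estimator copies
  gradients from the aggregator input back to the encoder output.
- **Aggregator** `g : Ẑ -> C`. A causal convolutional network (kernel sizes
  growing from 2, layer normalization, residual connections, dropout) whose
  context vector `c_t` sees only `ẑ_{<=t}`.
- **Objective.**
  `L = Σ_{k=1..K} L_k^CPC + ||sg(z) − ẑ||² + γ ||z − sg(ẑ)||²`,
  where each `L_k^CPC` is an InfoNCE term: a per-step linear head scores the
  true quantized latent k steps ahead against N negatives drawn from the
  batch (K = 10, N = 10, γ = 0.25). The codebook term trains only the
  codebook; the commitment term only the encoder; the contrastive term
  everything except the codebook.
- **Classifier.** Window tuples are indexed into a vocabulary with
  START/END/PAD/UNK specials and fed through an embedding layer, a two-layer
  GRU/LSTM (128 units), and an MLP (256, 128, n_classes) with batch
  normalization, ReLU and dropout. Evaluation is participant-wise five-fold
  cross-validation with macro-F1.
- **Baselines and extensions.** SAX on the acceleration magnitude and
  SAX-REPEAT (per-channel SAX + K-means over tuples, k = 512) produce token
  corpora for the identical classifier; a RoBERTa-style masked-token
  transformer can be pre-trained on the symbol corpus and used as frozen
  contextual embeddings.

All networks, including backpropagation, are implemented in base R; the
gradients are verified against finite differences in the test suite. A
synthetic wrist-accelerometry generator (gravity + activity-specific
harmonics + per-subject gain/phase variation + Gaussian noise) makes every
stage runnable and testable without external data.

## Worked example

Desk-scale end-to-end run on the packaged three-class benchmark (still /
walk-like / run-like, 6 subjects):

```r
library(vqcpc)

cfg <- default_benchmark(seed = 11)
recs <- generate_dataset(cfg)
windows <- unlist(lapply(recs, make_windows, window_s = 2, overlap_frac = 0.5),
                  recursive = FALSE)
folds <- make_participant_folds(sapply(recs, function(r) r$subject_id), seed = 42)
subj <- sapply(windows, function(w) w$subject_id)
tr <- subj %in% folds[[1]]$train

stats <- fit_normalization(windows[tr])       # train split only
windows <- apply_normalization(windows, stats)

model <- vqcpc_model(encoder_config(channels = c(8, 16, 16, 32)),
                     n_agg_blocks = 2, G = 2, V = 16, seed = 7)
pt <- pretrain(model, windows[tr], windows[subj %in% folds[[1]]$val],
               pretrain_config(lr = 3e-3, batch = 8, max_epochs = 5,
                               patience_start = 4, seed = 5))
seqs <- discretize(pt$model, windows)
head(seqs[[1]], 8)
#> "10-12" "10-12" "10-12" "10-12" "10-12" "10-12" "10-12" "10-12"
vocab <- build_vocabulary(seqs[tr])
vocab
#> <vocabulary> 16 tokens (12 tuples + 4 specials)
```

Each window is now a string of 49 two-group codeword tuples; this near-static
window repeats one symbol, and the whole training split uses only 12 distinct
tuples out of a possible 16² = 256. Training the GRU classifier on the token
sequences of fold 1:

```r
va <- subj %in% folds[[1]]$val; te <- subj %in% folds[[1]]$test
sub <- function(k) { s <- seqs[k]; attr(s, "label") <- attr(seqs, "label")[k]; s }
ccfg <- classifier_config(embedding_dim = 16, rnn_units = 32, rnn_layers = 1,
                          mlp_hidden = c(32, 16), batch = 64, epochs = 15, seed = 3)
m <- train_classifier(token_dataset(sub(tr), vocab, length_out = 51),
                      token_dataset(sub(va), vocab, length_out = 51),
                      ccfg, vocab_size = vocab$size)
pred <- predict_classifier(m, token_dataset(sub(te), vocab, length_out = 51))
macro_f1(pred, attr(seqs, "label")[te], classes = m$classes)
#> [1] 0.875
```

Held-out subjects are classified from the symbol strings alone with macro-F1
0.875 on this fold; with the benchmark's acceptance settings the pipeline
averages ≈ 0.98 over three seeds (computed in
`tests/testthat/test-acceptance.R`).
`symbol_histograms(seqs)` tabulates per-activity symbol usage, and
`codebook_stats()` reports usage perplexity and the effective joint alphabet.

`run_pipeline(run_config())` executes the same flow end to end and writes
recordings, windows, loss curves, the token corpus, and the evaluation
report to disk; `inst/scripts/vqcpc.R` wraps it for the shell.

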