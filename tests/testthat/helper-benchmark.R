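# Shared desk-scale benchmark fixtures, cached across test files.
.bench_cache <- new.env(parent = emptyenv())

# windows + folds for the packaged synthetic benchmark
benchmark_data <- function(seed = 11L) {
  key <- paste0("data", seed)
  if (!exists(key, .bench_cache)) {
    cfg <- default_benchmark(seed = seed)
    recs <- generate_dataset(cfg)
    windows <- unlist(lapply(recs, make_windows, window_s = 2,
                             overlap_frac = 0.5), recursive = FALSE)
    folds <- make_participant_folds(vapply(recs, `[[`, "", "subject_id"),
                                    seed = derive_seed(seed, "folds"))
    subj <- window_subjects(windows)
    f1 <- folds[[1L]]
    tr <- subj %in% f1$train
    stats <- fit_normalization(windows[tr])
    windows <- apply_normalization(windows, stats)
    assign(key, list(windows = windows, folds = folds, subj = subj,
                     train = tr, val = subj %in% f1$val,
                     test = subj %in% f1$test, stats = stats), .bench_cache)
  }
  get(key, .bench_cache)
}

tiny_benchmark_model <- function(seed, G = 2L, V = 16L) {
  vqcpc_model(encoder_config(channels = c(8L, 16L, 16L, 32L)),
              n_agg_blocks = 2L, G = G, V = V, K = 10L, n_negatives = 10L,
              seed = seed)
}

# 5-epoch pretrained tiny model on benchmark fold 1 (cached per seed)
benchmark_pretrained <- function(seed = 1L, data_seed = 11L) {
  key <- paste0("pt", seed, "_", data_seed)
  if (!exists(key, .bench_cache)) {
    d <- benchmark_data(data_seed)
    model <- tiny_benchmark_model(derive_seed(seed, "bench-model"))
    ptc <- pretrain_config(lr = 3e-3, batch = 8L, max_epochs = 5L,
                           patience_start = 4L,
                           seed = derive_seed(seed, "bench-pretrain"))
    pt <- pretrain(model, d$windows[d$train], d$windows[d$val], ptc)
    assign(key, pt, .bench_cache)
  }
  get(key, .bench_cache)
}

bench_classifier_config <- function(seed) {
  classifier_config(embedding_dim = 16L, rnn_units = 32L, rnn_layers = 1L,
                    mlp_hidden = c(32L, 16L), lr = 1e-3, batch = 64L,
                    epochs = 15L, seed = seed)
}

# train the shared classifier on a token corpus and report test macro-F1
bench_eval_tokens <- function(seqs, d, seed) {
  sub <- function(keep) {
    s <- seqs[keep]
    attr(s, "label") <- attr(seqs, "label")[keep]
    s
  }
  vocab <- build_vocabulary(sub(d$train))
  L <- max(lengths(seqs)) + 2L
  dtr <- token_dataset(sub(d$train), vocab, length_out = L)
  dva <- token_dataset(sub(d$val), vocab, length_out = L)
  dte <- token_dataset(sub(d$test), vocab, length_out = L)
  m <- train_classifier(dtr, dva, bench_classifier_config(seed),
                        vocab_size = vocab$size)
  pred <- predict_classifier(m, dte)
  macro_f1(pred, dte$labels, classes = m$classes)
}

# one full benchmark run: VQ-CPC tokens vs SAX-magnitude tokens under the
# identical classifier
run_benchmark <- function(seed) {
  data_seed <- derive_seed(seed, "bench-data")
  d <- benchmark_data(data_seed)
  pt <- benchmark_pretrained(seed, data_seed)
  vq_seqs <- discretize(pt$model, d$windows)
  sax_seqs <- sax_corpus(d$windows, sax_config())
  clf_seed <- derive_seed(seed, "bench-clf")
  list(vq_f1 = bench_eval_tokens(vq_seqs, d, clf_seed),
       sax_f1 = bench_eval_tokens(sax_seqs, d, clf_seed),
       model = pt$model, data = d, vq_seqs = vq_seqs)
}
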