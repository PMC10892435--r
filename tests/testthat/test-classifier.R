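toy_corpus <- function(n_per_class = 40L, seed = 5L) {
  # linearly separable: each class has its own token
  with_seed(seed, {
    seqs <- list()
    labels <- character(0)
    subjects <- character(0)
    for (cl in c("A", "B", "C")) {
      for (i in seq_len(n_per_class)) {
        tok <- paste0(match(cl, c("A", "B", "C")), "-1")
        filler <- sprintf("9-%d", sample(1:3, 3L, replace = TRUE))
        seqs[[length(seqs) + 1L]] <- c(sample(c(rep(tok, 3L), filler)), tok)
        labels <- c(labels, cl)
        subjects <- c(subjects, sprintf("P%d", (i %% 5L) + 1L))
      }
    }
    attr(seqs, "label") <- labels
    attr(seqs, "subject") <- subjects
    seqs
  })
}

toy_config <- function(seed = 1L, epochs = 5L) {
  classifier_config(embedding_dim = 8L, rnn_units = 12L, rnn_layers = 1L,
                    mlp_hidden = c(12L, 8L), lr = 5e-3, batch = 8L,
                    epochs = epochs, seed = seed)
}

test_that("macro-F1 matches confusion-matrix arithmetic", {
  expect_equal(macro_f1(c("a", "b"), c("a", "b")), 1.0)
  # balanced binary, everything predicted positive
  pred <- rep("pos", 10)
  truth <- rep(c("pos", "neg"), 5)
  expect_equal(macro_f1(pred, truth), 1 / 3)
  # arbitrary small case against a brute-force per-class computation
  with_seed(13, {
    for (rep in 1:5) {
      classes <- c("x", "y", "z")
      truth <- sample(classes, 40, replace = TRUE)
      pred <- sample(classes, 40, replace = TRUE)
      oracle <- mean(vapply(classes, function(cl) {
        tp <- sum(pred == cl & truth == cl)
        prec <- if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl)
        rec <- if (sum(truth == cl) == 0) 0 else tp / sum(truth == cl)
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      }, numeric(1)))
      expect_equal(macro_f1(pred, truth, classes), oracle)
    }
  })
  # a class absent from both vectors still counts as zero
  expect_equal(macro_f1(c("a", "a"), c("a", "a"), classes = c("a", "b")), 0.5)
})

test_that("a separable token corpus is classified perfectly within a few epochs", {
  seqs <- toy_corpus()
  vocab <- build_vocabulary(seqs)
  data <- token_dataset(seqs, vocab)
  m <- train_classifier(data, data, toy_config(), vocab_size = vocab$size)
  expect_equal(m$val_f1, 1.0)
})

test_that("classifier training is deterministic given the seed", {
  seqs <- toy_corpus(10L)
  vocab <- build_vocabulary(seqs)
  data <- token_dataset(seqs, vocab)
  m1 <- train_classifier(data, data, toy_config(seed = 9L, epochs = 2L),
                         vocab_size = vocab$size)
  m2 <- train_classifier(data, data, toy_config(seed = 9L, epochs = 2L),
                         vocab_size = vocab$size)
  expect_identical(m1$params, m2$params)
  m3 <- train_classifier(data, data, toy_config(seed = 10L, epochs = 2L),
                         vocab_size = vocab$size)
  expect_false(identical(m1$params, m3$params))
})

test_that("unseen validation labels are a configuration error", {
  seqs <- toy_corpus(5L)
  vocab <- build_vocabulary(seqs)
  data <- token_dataset(seqs, vocab)
  bad <- data
  bad$labels[1] <- "D"
  expect_error(train_classifier(data, bad, toy_config(),
                                vocab_size = vocab$size),
               class = "vqcpc_config_error")
})

test_that("an LSTM head trains on the same corpus", {
  seqs <- toy_corpus(10L)
  vocab <- build_vocabulary(seqs)
  data <- token_dataset(seqs, vocab)
  cfg <- toy_config(epochs = 5L)
  cfg$rnn_type <- "lstm"
  m <- train_classifier(data, data, cfg, vocab_size = vocab$size)
  expect_gt(m$val_f1, 0.9)
})

test_that("cross-validation selects from the grid without touching test labels", {
  seqs <- toy_corpus(20L)
  folds <- make_participant_folds(unique(attr(seqs, "subject")), seed = 2L)
  cv <- cross_validate(seqs, folds[1:2], cfg = toy_config(epochs = 4L),
                       lr_grid = 5e-3, l2_grid = 0, n_runs = 2L)
  expect_equal(cv$best$lr, 5e-3)
  expect_equal(cv$best$l2, 0)
  expect_equal(dim(cv$per_fold), c(2L, 2L))
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 1))
  # sd is across runs, not folds
  expect_equal(cv$sd_f1, stats::sd(rowMeans(cv$per_fold)))
  # participant-wise separation between train and test inside each fold
  for (f in folds) expect_length(intersect(f$train, f$test), 0L)
})
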