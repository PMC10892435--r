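#' Token-sequence classifier configuration
#'
#' Defaults follow the downstream recognition setup: a learnable 128-unit
#' embedding feeding a two-layer GRU (or LSTM) of 128 units with dropout
#' 0.2, whose final hidden state at the last non-PAD token enters an MLP of
#' (256, 128, n_classes) units with batch normalization, ReLU and dropout
#' between layers. Training uses Adam, batch 256, 50 epochs, learning rate
#' decayed by 0.8 every 10 epochs; lr and L2 are tuned over
#' {1e-3, 1e-4, 5e-4} and {0, 1e-4, 1e-5} in [cross_validate()].
#'
#' @param embedding_dim Embedding width (ignored with frozen embeddings).
#' @param rnn_type `"gru"` or `"lstm"`.
#' @param rnn_units,rnn_layers Recurrent width and depth.
#' @param dropout_p Dropout probability.
#' @param mlp_hidden Hidden sizes of the MLP head.
#' @param lr,l2 Learning rate and weight decay.
#' @param batch,epochs Batch size and epoch count.
#' @param lr_decay,lr_decay_every Step decay factor and interval.
#' @param seed Integer seed.
#' @return A `vqcpc_classifier_config`.
#' @export
classifier_config <- function(embedding_dim = 128L, rnn_type = c("gru", "lstm"),
                              rnn_units = 128L, rnn_layers = 2L,
                              dropout_p = 0.2, mlp_hidden = c(256L, 128L),
                              lr = 1e-3, l2 = 0, batch = 256L, epochs = 50L,
                              lr_decay = 0.8, lr_decay_every = 10L,
                              seed = 1L) {
  rnn_type <- match.arg(rnn_type)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 rnn_type = rnn_type, rnn_units = as.integer(rnn_units),
                 rnn_layers = as.integer(rnn_layers), dropout_p = dropout_p,
                 mlp_hidden = as.integer(mlp_hidden), lr = lr, l2 = l2,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed)),
            class = "vqcpc_classifier_config")
}

#' Assemble a token dataset for the classifier
#'
#' Encodes tuple sequences with a fixed vocabulary, pads to a common length,
#' and binds labels.
#'
#' @param sequences List of tuple-string vectors (e.g. from [discretize()]).
#' @param vocab A [build_vocabulary()] vocabulary (train split only).
#' @param labels Label per sequence (default: `label` attribute).
#' @param length_out Common padded length (default: longest sequence).
#' @return List with `ids`, `mask`, `labels`.
#' @export
token_dataset <- function(sequences, vocab,
                          labels = attr(sequences, "label"),
                          length_out = NULL) {
  enc <- lapply(sequences, encode_sequence, vocab = vocab)
  pb <- pad_batch(enc, length_out)
  list(ids = pb$ids, mask = pb$mask, labels = as.character(labels))
}

init_classifier <- function(cfg, vocab_size, n_classes, frozen_dim = NULL,
                            seed = 1L) {
  with_seed(seed, {
    e <- frozen_dim %||% cfg$embedding_dim
    params <- list()
    if (is.null(frozen_dim)) {
      params$emb <- matrix(stats::rnorm(vocab_size * e, 0, 0.1),
                           nrow = vocab_size)
    }
    in_dim <- e
    for (l in seq_len(cfg$rnn_layers)) {
      params[[paste0("rnn", l)]] <- init_rnn_layer(cfg$rnn_type, in_dim,
                                                   cfg$rnn_units)
      in_dim <- cfg$rnn_units
    }
    dims <- c(cfg$rnn_units, cfg$mlp_hidden, n_classes)
    for (l in seq_len(length(dims) - 1L)) {
      bound <- 1 / sqrt(dims[l])
      layer <- list(W = matrix(stats::runif(dims[l] * dims[l + 1L],
                                            -bound, bound), nrow = dims[l]),
                    b = numeric(dims[l + 1L]))
      if (l < length(dims) - 1L) {
        layer$bn_g <- rep(1, dims[l + 1L])
        layer$bn_b <- numeric(dims[l + 1L])
      }
      params[[paste0("mlp", l)]] <- layer
    }
    params
  })
}

# forward through embedding -> stacked RNN -> MLP head; returns logits and
# caches; `running` carries batch-norm running statistics
classifier_forward <- function(params, cfg, ids, mask, running, train,
                               embedder = NULL) {
  B <- nrow(ids); L <- ncol(ids)
  if (is.null(embedder)) {
    e <- ncol(params$emb)
    X <- array(t(params$emb[as.vector(ids) + 1L, , drop = FALSE]),
               dim = c(e, B, L))
    X <- aperm(X, c(2L, 3L, 1L))
  } else {
    X <- embedder(ids, mask)
  }
  caches <- list(ids = ids, emb_in = NULL)
  H <- X
  for (l in seq_len(cfg$rnn_layers)) {
    fn <- if (cfg$rnn_type == "gru") gru_forward else lstm_forward
    rf <- fn(params[[paste0("rnn", l)]], H, mask)
    dp <- NULL
    if (l < cfg$rnn_layers) {
      dp <- dropout_forward(rf$out, cfg$dropout_p, train)
      H <- dp$out
    } else {
      H <- rf$out
    }
    caches[[paste0("rnn", l)]] <- list(rnn = rf$caches,
                                       drop = if (is.null(dp)) NULL else dp$mask)
  }
  h <- rf$h_final
  n_mlp <- length(cfg$mlp_hidden) + 1L
  A <- h
  for (l in seq_len(n_mlp)) {
    p <- params[[paste0("mlp", l)]]
    lin <- sweep(A %*% p$W, 2L, p$b, "+")
    if (l < n_mlp) {
      key <- paste0("mlp", l)
      bn <- batchnorm_forward(lin, p$bn_g, p$bn_b, running[[key]], train)
      running[[key]] <- bn$running
      rl <- relu_forward(bn$out)
      dp <- dropout_forward(rl$out, cfg$dropout_p, train)
      caches[[key]] <- list(A = A, bn = bn$cache, relu = rl$mask,
                            drop = dp$mask)
      A <- dp$out
    } else {
      caches[[paste0("mlp", l)]] <- list(A = A)
      A <- lin
    }
  }
  list(logits = A, caches = caches, running = running)
}

classifier_backward <- function(params, cfg, dlogits, caches, mask,
                                frozen = FALSE) {
  grads <- list()
  n_mlp <- length(cfg$mlp_hidden) + 1L
  dA <- dlogits
  for (l in rev(seq_len(n_mlp))) {
    key <- paste0("mlp", l)
    ca <- caches[[key]]
    p <- params[[key]]
    if (l < n_mlp) {
      dA <- dropout_backward(dA, ca$drop)
      dA <- dA * ca$relu
      bn <- batchnorm_backward(dA, ca$bn)
      grads[[key]] <- list(W = crossprod(ca$A, bn$dX), b = colSums(bn$dX),
                           bn_g = bn$dg, bn_b = bn$db)
      dA <- bn$dX %*% t(p$W)
    } else {
      grads[[key]] <- list(W = crossprod(ca$A, dA), b = colSums(dA))
      dA <- dA %*% t(p$W)
    }
  }
  dHfinal <- dA
  B <- nrow(dHfinal)
  dOutZero <- NULL
  for (l in rev(seq_len(cfg$rnn_layers))) {
    key <- paste0("rnn", l)
    ca <- caches[[key]]
    fn <- if (cfg$rnn_type == "gru") gru_backward else lstm_backward
    L <- length(ca$rnn)
    if (is.null(dOutZero)) {
      dOut <- array(0, dim = c(B, L, cfg$rnn_units))
    } else {
      dOut <- dropout_backward(dOutZero, ca$drop)
    }
    bw <- fn(params[[key]], ca$rnn, dOut, dHfinal)
    grads[[key]] <- bw$grads
    dHfinal <- matrix(0, B, if (l > 1L) cfg$rnn_units else 0L)
    dOutZero <- bw$dX
    if (l > 1L) dHfinal <- matrix(0, B, cfg$rnn_units)
  }
  if (!frozen) {
    dX <- dOutZero                      # gradient w.r.t. the embedded input
    e <- dim(dX)[3]
    dEm <- matrix(aperm(dX, c(2L, 1L, 3L)), ncol = e)
    ids_flat <- as.vector(t(caches$ids)) + 1L
    dEmb <- scatter_add_rows(matrix(0, nrow(params$emb), e), ids_flat, dEm)
    grads$emb <- dEmb
  }
  grads
}

classifier_predict_logits <- function(model, ids, mask) {
  classifier_forward(model$params, model$cfg, ids, mask, model$running,
                     train = FALSE, embedder = model$embedder)$logits
}

#' Predict class labels for a token dataset
#'
#' @param model A trained classifier from [train_classifier()].
#' @param data A [token_dataset()].
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, data) {
  logits <- classifier_predict_logits(model, data$ids, data$mask)
  model$classes[max.col(logits, ties.method = "first")]
}

#' Train the token-sequence activity classifier
#'
#' Adam with stepped learning-rate decay; the class set is fixed from the
#' training split (a validation label unseen in training is a configuration
#' error). If `embedder` is supplied (e.g. a frozen masked-LM encoder via
#' [lm_embedder()]), it replaces the learnable embedding layer and receives
#' no updates.
#'
#' @param train,val [token_dataset()]s.
#' @param cfg A [classifier_config()].
#' @param vocab_size Vocabulary size (needed for the learnable embedding).
#' @param embedder Optional frozen embedding function
#'   `function(ids, mask) -> B x L x e` array.
#' @param verbose Print per-epoch progress.
#' @return List with `params`, `cfg`, `classes`, `running`, `embedder`,
#'   `val_f1`, and per-epoch `history`.
#' @export
train_classifier <- function(train, val, cfg = classifier_config(),
                             vocab_size = NULL, embedder = NULL,
                             verbose = FALSE) {
  classes <- sort(unique(train$labels))
  if (!all(val$labels %in% classes)) {
    stop_vqcpc("validation labels absent from the training split",
               "vqcpc_config_error")
  }
  y <- match(train$labels, classes)
  frozen_dim <- NULL
  if (!is.null(embedder)) {
    frozen_dim <- dim(embedder(train$ids[1L, , drop = FALSE],
                               train$mask[1L, , drop = FALSE]))[3]
  } else if (is.null(vocab_size)) {
    stop_vqcpc("vocab_size is required for a learnable embedding",
               "vqcpc_config_error")
  }
  n_classes <- length(classes)
  params <- init_classifier(cfg, vocab_size, n_classes,
                            frozen_dim = frozen_dim,
                            seed = derive_seed(cfg$seed, "clf-init"))
  running <- list()
  for (l in seq_along(cfg$mlp_hidden)) {
    running[[paste0("mlp", l)]] <- list(mean = numeric(cfg$mlp_hidden[l]),
                                        var = rep(1, cfg$mlp_hidden[l]))
  }
  opt <- adam_init(params)
  n <- nrow(train$ids)
  history <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr * cfg$lr_decay^((epoch - 1L) %/% cfg$lr_decay_every)
      ord <- sample.int(n)
      n_batches <- ceiling(n / cfg$batch)
      ep_loss <- 0
      for (bi in seq_len(n_batches)) {
        take <- ord[((bi - 1L) * cfg$batch + 1L):min(bi * cfg$batch, n)]
        fw <- classifier_forward(params, cfg,
                                 train$ids[take, , drop = FALSE],
                                 train$mask[take, , drop = FALSE],
                                 running, train = TRUE, embedder = embedder)
        running <- fw$running
        ce <- softmax_xent(fw$logits, y[take])
        ep_loss <- ep_loss + ce$loss
        grads <- classifier_backward(params, cfg, ce$dlogits, fw$caches,
                                     train$mask[take, , drop = FALSE],
                                     frozen = !is.null(embedder))
        grads <- grads[names(params)]
        st <- adam_step(params, grads, opt, lr = lr, weight_decay = cfg$l2)
        params <- st$params
        opt <- st$state
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / n_batches))
      if (verbose) message(sprintf("epoch %d: loss %.4f", epoch,
                                   ep_loss / n_batches))
    }
  })
  # recalibrate batch-norm statistics under the final weights: one
  # stats-only pass over the training set with dropout disabled, so the
  # eval-time normalizers match the distributions the MLP actually sees
  cfg0 <- cfg
  cfg0$dropout_p <- 0
  for (l in seq_along(cfg$mlp_hidden)) {
    running[[paste0("mlp", l)]] <- list(mean = numeric(cfg$mlp_hidden[l]),
                                        var = rep(1, cfg$mlp_hidden[l]),
                                        n = 0)
  }
  for (bi in seq_len(ceiling(n / cfg$batch))) {
    take <- ((bi - 1L) * cfg$batch + 1L):min(bi * cfg$batch, n)
    fw <- classifier_forward(params, cfg0, train$ids[take, , drop = FALSE],
                             train$mask[take, , drop = FALSE], running,
                             train = TRUE, embedder = embedder)
    running <- fw$running
  }
  model <- list(params = params, cfg = cfg, classes = classes,
                running = running, embedder = embedder)
  pred <- predict_classifier(model, val)
  model$val_f1 <- macro_f1(pred, val$labels, classes = classes)
  model$history <- history
  model
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of per-class F1; a class absent from both
#' predictions and truth (but present in `classes`) contributes 0.
#'
#' @param predictions,labels Vectors of equal length.
#' @param classes The class set (default: union of both vectors).
#' @return A score in `[0, 1]`.
#' @export
macro_f1 <- function(predictions, labels, classes = NULL) {
  stopifnot(length(predictions) == length(labels))
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  classes <- classes %||% sort(unique(c(predictions, labels)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Participant-wise cross-validation with hyperparameter selection
#'
#' For every (lr, l2) combination the classifier is trained on each fold and
#' the validation macro-F1 is averaged across folds; the best combination is
#' then retrained with `n_runs` seeds and the per-fold test macro-F1 is
#' reported as mean and standard deviation across runs (sd over runs, not
#' folds). Hyperparameters are never selected on test data; the vocabulary
#' is rebuilt per fold from that fold's training subjects only.
#'
#' @param sequences List of tuple-string vectors with `label` and `subject`
#'   attributes (as produced by [discretize()]).
#' @param folds Folds from [make_participant_folds()].
#' @param cfg Base [classifier_config()].
#' @param lr_grid,l2_grid Hyperparameter grids.
#' @param n_runs Randomized runs for the final report (default 5).
#' @param embedder Optional frozen embedding function.
#' @param verbose Print progress.
#' @return List with `best` (chosen lr/l2), `val_scores` (grid data.frame),
#'   `per_fold` (test F1 per fold and run), `mean_f1`, `sd_f1`.
#' @export
cross_validate <- function(sequences, folds, cfg = classifier_config(),
                           lr_grid = c(1e-3, 1e-4, 5e-4),
                           l2_grid = c(0, 1e-4, 1e-5), n_runs = 5L,
                           embedder = NULL, verbose = FALSE) {
  labels <- attr(sequences, "label")
  subjects <- attr(sequences, "subject")
  fold_data <- function(fold) {
    mk <- function(subj) {
      keep <- subjects %in% subj
      s <- sequences[keep]
      attr(s, "label") <- labels[keep]
      s
    }
    tr <- mk(fold$train)
    vocab <- build_vocabulary(tr)
    L <- max(lengths(lapply(sequences, identity))) + 2L
    list(train = token_dataset(tr, vocab, length_out = L),
         val = token_dataset(mk(fold$val), vocab,
                             labels = labels[subjects %in% fold$val],
                             length_out = L),
         test = token_dataset(mk(fold$test), vocab,
                              labels = labels[subjects %in% fold$test],
                              length_out = L),
         vocab = vocab)
  }
  datasets <- lapply(folds, fold_data)
  grid <- expand.grid(lr = lr_grid, l2 = l2_grid)
  grid$val_f1 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    scores <- vapply(datasets, function(d) {
      cfg_i <- cfg
      cfg_i$lr <- grid$lr[i]
      cfg_i$l2 <- grid$l2[i]
      m <- train_classifier(d$train, d$val, cfg_i,
                            vocab_size = d$vocab$size, embedder = embedder)
      m$val_f1
    }, numeric(1))
    grid$val_f1[i] <- mean(scores)
    if (verbose) {
      message(sprintf("lr=%g l2=%g: val F1 %.3f", grid$lr[i], grid$l2[i],
                      grid$val_f1[i]))
    }
  }
  best <- grid[which.max(grid$val_f1), ]
  per_fold <- matrix(NA_real_, n_runs, length(folds))
  for (r in seq_len(n_runs)) {
    for (f in seq_along(folds)) {
      cfg_r <- cfg
      cfg_r$lr <- best$lr
      cfg_r$l2 <- best$l2
      cfg_r$seed <- derive_seed(cfg$seed, "cv-run", r * 100L + f)
      d <- datasets[[f]]
      m <- train_classifier(d$train, d$val, cfg_r,
                            vocab_size = d$vocab$size, embedder = embedder)
      pred <- predict_classifier(m, d$test)
      per_fold[r, f] <- macro_f1(pred, d$test$labels, classes = m$classes)
    }
  }
  run_means <- rowMeans(per_fold)
  list(best = list(lr = best$lr, l2 = best$l2), val_scores = grid,
       per_fold = per_fold, mean_f1 = mean(run_means),
       sd_f1 = stats::sd(run_means))
}
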