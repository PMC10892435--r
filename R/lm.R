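#' Masked-token language model configuration
#'
#' Two standard sizes: `"small"` (embedding 128, feedforward 512, 2
#' transformer-encoder layers, 8 heads) and `"medium"` (256/1024/4 layers/8
#' heads). Masking selects 15% of non-special, non-PAD positions; of those,
#' 80% become the MASK token, 10% a random ordinary token, 10% stay
#' unchanged. The MASK token is internal to the LM (id = vocabulary size).
#'
#' @param size `"small"` or `"medium"`.
#' @param mask_prob Masking probability (default 0.15).
#' @param mask_split Length-3 MASK/random/keep split (default 80/10/10).
#' @param max_seq Maximum (padded) sequence length for the learned
#'   positional embeddings (default 64).
#' @param lr,l2 Adam learning rate and weight decay.
#' @param batch,epochs Batch size and training epochs.
#' @param seed Integer seed.
#' @return A `vqcpc_lm_config`.
#' @export
lm_config <- function(size = c("small", "medium"), mask_prob = 0.15,
                      mask_split = c(0.8, 0.1, 0.1), max_seq = 64L,
                      lr = 1e-3, l2 = 0, batch = 16L, epochs = 30L,
                      seed = 1L) {
  size <- match.arg(size)
  dims <- if (size == "small") {
    list(e = 128L, ff = 512L, layers = 2L, heads = 8L)
  } else {
    list(e = 256L, ff = 1024L, layers = 4L, heads = 8L)
  }
  stopifnot(mask_prob > 0, mask_prob <= 1,
            abs(sum(mask_split) - 1) < 1e-9, dims$e %% dims$heads == 0L)
  structure(c(dims, list(size = size, mask_prob = mask_prob,
                         mask_split = mask_split, max_seq = as.integer(max_seq),
                         lr = lr, l2 = l2, batch = as.integer(batch),
                         epochs = as.integer(epochs), seed = as.integer(seed))),
            class = "vqcpc_lm_config")
}

#' Corrupt a token batch for masked-LM training
#'
#' @param ids Integer id matrix (n x L) from [pad_batch()].
#' @param mask Matching validity mask (1 = real token).
#' @param vocab_size Vocabulary size (MASK id = `vocab_size`).
#' @param cfg An [lm_config()].
#' @return List with `ids` (corrupted), `targets` (original ids at selected
#'   positions) and `positions` (n x L logical selection matrix). PAD and
#'   special tokens are never selected.
#' @export
mask_batch <- function(ids, mask, vocab_size, cfg = lm_config()) {
  maskable <- mask > 0 & ids >= 4L
  sel <- maskable & matrix(stats::runif(length(ids)) < cfg$mask_prob,
                           nrow(ids))
  out <- ids
  if (any(sel)) {
    u <- stats::runif(sum(sel))
    action <- ifelse(u < cfg$mask_split[1], "mask",
                     ifelse(u < cfg$mask_split[1] + cfg$mask_split[2],
                            "random", "keep"))
    repl <- ids[sel]
    repl[action == "mask"] <- vocab_size
    n_rand <- sum(action == "random")
    if (n_rand > 0 && vocab_size > 4L) {
      repl[action == "random"] <- sample(4:(vocab_size - 1L), n_rand,
                                         replace = TRUE)
    }
    out[sel] <- repl
  }
  # targets ordered row-major (by sequence, then position) to match the
  # flattened hidden-state layout used by lm_loss
  list(ids = out, targets = t(ids)[t(sel)], positions = sel)
}

init_lm <- function(cfg, vocab_size, seed = 1L) {
  with_seed(seed, {
    e <- cfg$e
    rn <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, 0, sd),
                                           nrow = n)
    # embeddings: small normal; linear maps: fan-in-scaled uniform
    lin <- function(n, m) matrix(stats::runif(n * m, -1 / sqrt(n),
                                              1 / sqrt(n)), nrow = n)
    params <- list(tok = rn(vocab_size + 1L, e), pos = rn(cfg$max_seq, e))
    for (l in seq_len(cfg$layers)) {
      params[[paste0("layer", l)]] <- list(
        Wq = lin(e, e), bq = numeric(e), Wk = lin(e, e), bk = numeric(e),
        Wv = lin(e, e), bv = numeric(e), Wo = lin(e, e), bo = numeric(e),
        ln1_g = rep(1, e), ln1_b = numeric(e),
        W1 = lin(e, cfg$ff), b1 = numeric(cfg$ff),
        W2 = lin(cfg$ff, e), b2 = numeric(e),
        ln2_g = rep(1, e), ln2_b = numeric(e))
    }
    params$Wout <- rn(e, vocab_size)
    params$bout <- numeric(vocab_size)
    params
  })
}

# multi-head self-attention with key padding mask; Xm rows ordered (b-1)*L+l
mha_forward <- function(p, Xm, B, L, heads, mask) {
  e <- ncol(Xm)
  dk <- e %/% heads
  Q <- sweep(Xm %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(Xm %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(Xm %*% p$Wv, 2L, p$bv, "+")
  O <- matrix(0, nrow(Xm), e)
  A_list <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    keymask <- mask[b, ] > 0
    A_list[[b]] <- vector("list", heads)
    for (h in seq_len(heads)) {
      sl <- ((h - 1L) * dk + 1L):(h * dk)
      S <- (Q[rows, sl, drop = FALSE] %*%
              t(K[rows, sl, drop = FALSE])) / sqrt(dk)
      S[, !keymask] <- -Inf
      A <- softmax_rows(S)
      A_list[[b]][[h]] <- A
      O[rows, sl] <- A %*% V[rows, sl, drop = FALSE]
    }
  }
  out <- sweep(O %*% p$Wo, 2L, p$bo, "+")
  list(out = out, cache = list(Q = Q, K = K, V = V, O = O, A = A_list,
                               B = B, L = L, heads = heads, dk = dk))
}

mha_backward <- function(p, dY, Xm, cache) {
  B <- cache$B; L <- cache$L; heads <- cache$heads; dk <- cache$dk
  dO <- dY %*% t(p$Wo)
  dWo <- crossprod(cache$O, dY)
  dbo <- colSums(dY)
  dQ <- matrix(0, nrow(Xm), ncol(Xm))
  dK <- matrix(0, nrow(Xm), ncol(Xm))
  dV <- matrix(0, nrow(Xm), ncol(Xm))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(heads)) {
      sl <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cache$A[[b]][[h]]
      dOh <- dO[rows, sl, drop = FALSE]
      Vb <- cache$V[rows, sl, drop = FALSE]
      dA <- dOh %*% t(Vb)
      dV[rows, sl] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, sl] <- (dS %*% cache$K[rows, sl, drop = FALSE]) / sqrt(dk)
      dK[rows, sl] <- (crossprod(dS, cache$Q[rows, sl, drop = FALSE])) /
        sqrt(dk)
    }
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       grads = list(Wq = crossprod(Xm, dQ), bq = colSums(dQ),
                    Wk = crossprod(Xm, dK), bk = colSums(dK),
                    Wv = crossprod(Xm, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

lm_forward <- function(params, cfg, ids, mask) {
  B <- nrow(ids); L <- ncol(ids)
  e <- cfg$e
  Xm <- params$tok[as.vector(t(ids)) + 1L, , drop = FALSE] +
    params$pos[rep(seq_len(L), B), , drop = FALSE]
  caches <- list(ids = ids, B = B, L = L)
  for (l in seq_len(cfg$layers)) {
    p <- params[[paste0("layer", l)]]
    at <- mha_forward(p, Xm, B, L, cfg$heads, mask)
    ln1 <- layernorm_forward(Xm + at$out, p$ln1_g, p$ln1_b)
    H1 <- ln1$out
    lin1 <- sweep(H1 %*% p$W1, 2L, p$b1, "+")
    rl <- relu_forward(lin1)
    ff <- sweep(rl$out %*% p$W2, 2L, p$b2, "+")
    ln2 <- layernorm_forward(H1 + ff, p$ln2_g, p$ln2_b)
    caches[[paste0("layer", l)]] <- list(Xin = Xm, at = at$cache,
                                         ln1 = ln1$cache, H1 = H1,
                                         relu = rl, ln2 = ln2$cache)
    Xm <- ln2$out
  }
  list(hidden = Xm, caches = caches)
}

lm_backward <- function(params, cfg, dH, caches, mask) {
  grads <- list()
  for (l in rev(seq_len(cfg$layers))) {
    key <- paste0("layer", l)
    p <- params[[key]]
    ca <- caches[[key]]
    l2 <- layernorm_backward(dH, ca$ln2)
    dFF <- l2$dX
    dH1 <- l2$dX                          # residual path
    drl <- (dFF %*% t(p$W2)) * ca$relu$mask
    dW2 <- crossprod(ca$relu$out, dFF)
    db2 <- colSums(dFF)
    dW1 <- crossprod(ca$H1, drl)
    db1 <- colSums(drl)
    dH1 <- dH1 + drl %*% t(p$W1)
    l1 <- layernorm_backward(dH1, ca$ln1)
    dAtt <- l1$dX
    dXin <- l1$dX                         # residual path
    ab <- mha_backward(p, dAtt, ca$Xin, ca$at)
    dXin <- dXin + ab$dX
    grads[[key]] <- c(ab$grads,
                      list(ln1_g = l1$dg, ln1_b = l1$db, W1 = dW1, b1 = db1,
                           W2 = dW2, b2 = db2, ln2_g = l2$dg, ln2_b = l2$db))
    dH <- dXin
  }
  ids_flat <- as.vector(t(caches$ids)) + 1L
  grads$tok <- scatter_add_rows(matrix(0, nrow(params$tok), cfg$e),
                                ids_flat, dH)
  grads$pos <- scatter_add_rows(matrix(0, cfg$max_seq, cfg$e),
                                rep(seq_len(caches$L), caches$B), dH)
  grads
}

#' Masked-LM loss (and gradients) on one batch
#'
#' Cross-entropy over the vocabulary at the selected positions only. At
#' random initialization the loss is close to `log(vocab_size)`.
#'
#' @param params LM parameters.
#' @param cfg An [lm_config()].
#' @param corrupted Output of [mask_batch()].
#' @param mask Validity mask matching the ids.
#' @param want_grads Compute gradients.
#' @return List with `loss` and optionally `grads`.
#' @export
lm_loss <- function(params, cfg, corrupted, mask, want_grads = FALSE) {
  if (!length(corrupted$targets)) {
    stop_vqcpc("no maskable positions in batch", "vqcpc_no_maskable")
  }
  fw <- lm_forward(params, cfg, corrupted$ids, mask)
  sel_flat <- which(as.vector(t(corrupted$positions)))
  H <- fw$hidden[sel_flat, , drop = FALSE]
  logits <- sweep(H %*% params$Wout, 2L, params$bout, "+")
  labels <- corrupted$targets + 1L
  ce <- softmax_xent(logits, labels)
  if (!want_grads) return(list(loss = ce$loss))
  dH_sel <- ce$dlogits %*% t(params$Wout)
  dHidden <- matrix(0, nrow(fw$hidden), cfg$e)
  dHidden[sel_flat, ] <- dH_sel
  grads <- lm_backward(params, cfg, dHidden, fw$caches, mask)
  grads$Wout <- crossprod(H, ce$dlogits)
  grads$bout <- colSums(ce$dlogits)
  list(loss = ce$loss, grads = grads)
}

#' Pre-train a masked-token LM on a symbol corpus
#'
#' RoBERTa-style dynamic masking: a fresh corruption pattern is drawn for
#' every batch; only masked positions contribute to the cross-entropy.
#' Deterministic given `cfg$seed`.
#'
#' @param corpus List of tuple-string vectors (training split only).
#' @param vocab The fixed [build_vocabulary()] vocabulary.
#' @param cfg An [lm_config()].
#' @param verbose Print per-epoch loss.
#' @return A `vqcpc_lm` with `params`, `cfg`, `vocab_size` and training-loss
#'   `history`.
#' @export
pretrain_lm <- function(corpus, vocab, cfg = lm_config(), verbose = FALSE) {
  enc <- lapply(corpus, encode_sequence, vocab = vocab)
  pb <- pad_batch(enc)
  if (ncol(pb$ids) > cfg$max_seq) {
    stop_vqcpc("sequences exceed the positional-embedding capacity",
               "vqcpc_config_error")
  }
  params <- init_lm(cfg, vocab$size, seed = derive_seed(cfg$seed, "lm-init"))
  opt <- adam_init(params)
  n <- nrow(pb$ids)
  history <- numeric(0)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      n_batches <- ceiling(n / cfg$batch)
      ep <- 0
      for (bi in seq_len(n_batches)) {
        take <- ord[((bi - 1L) * cfg$batch + 1L):min(bi * cfg$batch, n)]
        mb <- mask_batch(pb$ids[take, , drop = FALSE],
                         pb$mask[take, , drop = FALSE], vocab$size, cfg)
        if (!length(mb$targets)) next
        res <- lm_loss(params, cfg, mb, pb$mask[take, , drop = FALSE],
                       want_grads = TRUE)
        st <- adam_step(params, res$grads, opt, lr = cfg$lr,
                        weight_decay = cfg$l2)
        params <- st$params
        opt <- st$state
        ep <- ep + res$loss
      }
      history <- c(history, ep / n_batches)
      if (verbose) message(sprintf("epoch %d: masked loss %.4f", epoch,
                                   history[epoch]))
    }
  })
  structure(list(params = params, cfg = cfg, vocab_size = vocab$size,
                 history = history), class = "vqcpc_lm")
}

#' Contextual embeddings from a trained LM
#'
#' Final-encoder-layer hidden state per position; no parameter is updated.
#'
#' @param lm A [pretrain_lm()] model.
#' @param ids,mask Id and mask matrices.
#' @return B x L x e array of embeddings.
#' @export
lm_embed <- function(lm, ids, mask) {
  H <- lm_forward(lm$params, lm$cfg, ids, mask)$hidden
  mat2arr(H, nrow(ids), ncol(ids))
}

#' Frozen-embedding adapter for [train_classifier()]
#'
#' @param lm A trained [pretrain_lm()] model.
#' @return A `function(ids, mask)` returning frozen contextual embeddings.
#' @export
lm_embedder <- function(lm) {
  force(lm)
  function(ids, mask) lm_embed(lm, ids, mask)
}
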