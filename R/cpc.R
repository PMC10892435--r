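# (B, T, d) array <-> (B*T, d) row matrix with row index (b-1)*T + t
arr2mat <- function(A) matrix(aperm(A, c(2L, 1L, 3L)), ncol = dim(A)[3])
mat2arr <- function(M, B, Tt) aperm(array(M, dim = c(Tt, B, ncol(M))),
                                    c(2L, 1L, 3L))

#' Causal convolutional aggregator configuration
#'
#' The aggregator summarizes quantized latents up to time t into a context
#' vector c_t. Each block applies a causal (left-padded) 1-D convolution
#' with stride 1, layer normalization, ReLU and dropout, plus an identity
#' residual connection; kernel sizes grow consecutively from 2 (block b has
#' kernel b + 1). Channel width equals the latent dimension.
#'
#' @param n_blocks Number of blocks (tuned over 2, 4, 6).
#' @param channels Channel width (must equal the encoder's latent dim).
#' @param dropout_p Dropout probability (default 0.2).
#' @return An `vqcpc_aggregator_config`.
#' @export
aggregator_config <- function(n_blocks = 2L, channels = 256L,
                              dropout_p = 0.2) {
  structure(list(n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels),
                 kernels = seq_len(n_blocks) + 1L,
                 dropout_p = dropout_p),
            class = "vqcpc_aggregator_config")
}

#' Initialize aggregator parameters
#' @param cfg An [aggregator_config()].
#' @param seed Integer seed.
#' @return Parameter list, one block each with conv `W`/`b` and layer-norm
#'   gain/bias.
#' @export
init_aggregator <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$channels
    params <- list()
    for (i in seq_len(cfg$n_blocks)) {
      k <- cfg$kernels[i]
      bound <- 1 / sqrt(k * d)
      params[[paste0("block", i)]] <- list(
        W = matrix(stats::runif(k * d * d, -bound, bound), nrow = k * d),
        b = numeric(d), ln_g = rep(1, d), ln_b = numeric(d))
    }
    params
  })
}

aggregator_forward <- function(params, cfg, Zhat, train = FALSE) {
  B <- dim(Zhat)[1]; Tt <- dim(Zhat)[2]
  H <- Zhat
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    k <- cfg$kernels[i]
    P <- pad_left(H, k - 1L)
    cv <- conv1d_forward(P, params[[i]]$W, params[[i]]$b, k, 1L)
    Cm <- arr2mat(cv$out)
    ln <- layernorm_forward(Cm, params[[i]]$ln_g, params[[i]]$ln_b)
    rl <- relu_forward(ln$out)
    dp <- dropout_forward(rl$out, cfg$dropout_p, train)
    caches[[i]] <- list(conv = cv$cache, ln = ln$cache, relu = rl$mask,
                        drop = dp$mask, k = k)
    H <- H + mat2arr(dp$out, B, Tt)
  }
  list(out = H, caches = caches)
}

aggregator_backward <- function(dC, params, cfg, caches) {
  B <- dim(dC)[1]; Tt <- dim(dC)[2]
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  dH <- dC
  for (i in rev(seq_len(cfg$n_blocks))) {
    ca <- caches[[i]]
    dBranch <- arr2mat(dH)                     # gradient entering the block output
    dBranch <- dropout_backward(dBranch, ca$drop)
    dBranch <- dBranch * ca$relu
    ln <- layernorm_backward(dBranch, ca$ln)
    dConv <- mat2arr(ln$dX, B, Tt)
    bw <- conv1d_backward(dConv, ca$conv)
    grads[[i]] <- list(W = bw$dW, b = bw$db, ln_g = ln$dg, ln_b = ln$db)
    dH <- dH + unpad_left_grad(bw$dX, ca$k - 1L)   # residual + branch paths
  }
  list(dX = dH, grads = grads)
}

#' Aggregate quantized latents into causal context vectors
#'
#' @param params Parameters from [init_aggregator()].
#' @param cfg The matching [aggregator_config()].
#' @param Zhat Quantized latent batch (B x T' x d).
#' @param train Dropout active if `TRUE`.
#' @return Context batch (B x T' x d); c_t depends only on inputs up to t.
#' @export
aggregate_context <- function(params, cfg, Zhat, train = FALSE) {
  if (dim(Zhat)[3] != cfg$channels) {
    stop_vqcpc("aggregator channel width does not match input dim",
               "vqcpc_config_error")
  }
  aggregator_forward(params, cfg, Zhat, train = train)$out
}

#' Initialize the K per-step prediction heads
#'
#' One linear map W_k (d x d, no bias) per future offset k = 1..K; the
#' score of candidate u for anchor c_t at offset k is the dot product
#' `<W_k c_t, u>`.
#'
#' @param K Prediction horizon (default 10).
#' @param d Latent dimension.
#' @param seed Integer seed.
#' @return List of K weight matrices.
#' @export
init_heads <- function(K = 10L, d = 256L, seed = 1L) {
  with_seed(seed, {
    bound <- 1 / sqrt(d)
    lapply(seq_len(K), function(k) {
      matrix(stats::runif(d * d, -bound, bound), nrow = d)
    })
  })
}

# InfoNCE future prediction over all anchors; uses the current RNG stream
# for negative sampling. Returns per-k losses and (optionally) gradients.
cpc_forward_backward <- function(C, Zhat, heads, n_negatives,
                                 want_grads = TRUE) {
  B <- dim(C)[1]; Tt <- dim(C)[2]; d <- dim(C)[3]
  K <- length(heads)
  if (Tt <= K) {
    stop_vqcpc(sprintf("sequence length %d must exceed horizon K=%d", Tt, K),
               "vqcpc_config_error")
  }
  Cm <- arr2mat(C)
  pool <- arr2mat(Zhat)
  M <- nrow(pool)
  N <- n_negatives
  per_k <- numeric(K)
  dCm <- if (want_grads) matrix(0, M, d) else NULL
  dPool <- if (want_grads) matrix(0, M, d) else NULL
  dheads <- if (want_grads) vector("list", K) else NULL
  for (k in seq_len(K)) {
    mask <- rep(c(rep(TRUE, Tt - k), rep(FALSE, k)), B)
    anchors <- which(mask)
    pos <- anchors + k
    Mk <- length(anchors)
    P <- Cm[anchors, , drop = FALSE] %*% heads[[k]]
    r <- sample.int(M - 1L, Mk * N, replace = TRUE)
    neg <- matrix(r, Mk, N)
    neg <- neg + (neg >= pos)            # skip the positive's pool position
    S <- matrix(0, Mk, N + 1L)
    S[, 1L] <- rowSums(P * pool[pos, , drop = FALSE])
    for (j in seq_len(N)) {
      S[, j + 1L] <- rowSums(P * pool[neg[, j], , drop = FALSE])
    }
    ce <- softmax_xent(S, rep(1L, Mk))
    per_k[k] <- ce$loss
    if (want_grads) {
      dS <- ce$dlogits
      dP <- dS[, 1L] * pool[pos, , drop = FALSE]
      dPool <- scatter_add_rows(dPool, pos, dS[, 1L] * P)
      for (j in seq_len(N)) {
        dP <- dP + dS[, j + 1L] * pool[neg[, j], , drop = FALSE]
        dPool <- scatter_add_rows(dPool, neg[, j], dS[, j + 1L] * P)
      }
      dheads[[k]] <- crossprod(Cm[anchors, , drop = FALSE], dP)
      dCm[anchors, ] <- dCm[anchors, , drop = FALSE] + dP %*% t(heads[[k]])
    }
  }
  out <- list(per_k = per_k, total = sum(per_k))
  if (want_grads) {
    out$dC <- mat2arr(dCm, B, Tt)
    out$dZhat <- mat2arr(dPool, B, Tt)
    out$dheads <- dheads
  }
  out
}

#' Contrastive K-step future-prediction loss
#'
#' For every context vector c_t and offset k, the positive is the quantized
#' latent k steps ahead in the same window; N negatives are drawn uniformly
#' with replacement from all quantized latents in the batch (any window, any
#' step) excluding the positive's position. The loss is softmax
#' cross-entropy over the N+1 candidates, averaged over anchors, one term
#' per k. With all scores equal, each term is ln(N+1).
#'
#' @param C Context batch (B x T' x d) from [aggregate_context()].
#' @param Zhat Quantized target batch of the same shape.
#' @param heads Prediction heads from [init_heads()].
#' @param n_negatives Number of negatives N (default 10).
#' @param seed Optional seed making the negative draws reproducible.
#' @return List with `per_k` (length-K losses) and their `total`.
#' @export
cpc_loss <- function(C, Zhat, heads, n_negatives = 10L, seed = NULL) {
  run <- function() cpc_forward_backward(C, Zhat, heads, n_negatives,
                                         want_grads = FALSE)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  list(per_k = res$per_k, total = res$total)
}

#' Assemble a VQ-CPC model
#'
#' Bundles encoder, grouped codebook, causal aggregator and prediction heads
#' with a single parameter tree, ready for [total_loss()] and [pretrain()].
#'
#' @param enc_cfg An [encoder_config()].
#' @param n_agg_blocks Aggregator depth (default 2; tuned over 2/4/6).
#' @param G,V Codebook groups and per-group size (defaults 2 and 100).
#' @param gamma Commitment weight (default 0.25).
#' @param K Prediction horizon (default 10).
#' @param n_negatives Negatives per prediction (default 10).
#' @param seed Integer seed for all initializations.
#' @return A `vqcpc_model` list with `params` and `cfg`.
#' @export
vqcpc_model <- function(enc_cfg = encoder_config(), n_agg_blocks = 2L,
                        G = 2L, V = 100L, gamma = 0.25, K = 10L,
                        n_negatives = 10L, seed = 1L) {
  d <- enc_cfg$channels[length(enc_cfg$channels)]
  agg_cfg <- aggregator_config(n_agg_blocks, channels = d,
                               dropout_p = enc_cfg$dropout_p)
  cb <- init_codebook(G, V, d, seed = derive_seed(seed, "codebook"),
                      gamma = gamma)
  params <- list(
    enc = init_encoder(enc_cfg, seed = derive_seed(seed, "encoder")),
    cb = cb$vectors,
    agg = init_aggregator(agg_cfg, seed = derive_seed(seed, "aggregator")),
    heads = init_heads(K, d, seed = derive_seed(seed, "heads")))
  structure(list(params = params,
                 cfg = list(enc = enc_cfg, agg = agg_cfg, G = as.integer(G),
                            V = as.integer(V), d = d, gamma = gamma,
                            K = as.integer(K),
                            n_negatives = as.integer(n_negatives))),
            class = "vqcpc_model")
}

#' @export
print.vqcpc_model <- function(x, ...) {
  cat(sprintf(paste0("<vqcpc_model> d=%d, G=%d, V=%d, gamma=%g, K=%d, N=%d, ",
                     "%d aggregator block(s)\n"),
              x$cfg$d, x$cfg$G, x$cfg$V, x$cfg$gamma, x$cfg$K,
              x$cfg$n_negatives, x$cfg$agg$n_blocks))
  invisible(x)
}

model_codebook <- function(model) {
  structure(list(G = model$cfg$G, V = model$cfg$V, d = model$cfg$d,
                 dg = model$cfg$d %/% model$cfg$G, gamma = model$cfg$gamma,
                 vectors = model$params$cb),
            class = "vqcpc_codebook")
}

# full objective with gradients; uses the current RNG stream (dropout +
# negative sampling). Gradient routing:
#   - CPC term: aggregator + heads + (straight-through) encoder; never codebook
#   - codebook term: codebook rows only
#   - commitment term (gamma-weighted): encoder only
#   `term_weights` scales the gradient contribution of each loss term
#   (cpc, codebook, commitment) without changing the reported values;
#   used to verify the routing above by ablation.
model_forward_backward <- function(model, X, train = TRUE,
                                   want_grads = TRUE,
                                   term_weights = c(cpc = 1, codebook = 1,
                                                    commitment = 1)) {
  cfg <- model$cfg
  p <- model$params
  ef <- encoder_forward(p$enc, cfg$enc, X, train = train)
  Z <- ef$out
  B <- dim(Z)[1]; Tt <- dim(Z)[2]
  cb <- model_codebook(model)
  q <- quantize(Z, cb)
  Zhat <- q$z_hat
  M <- B * Tt
  diffZ <- Z - Zhat
  d2 <- sum(diffZ * diffZ) / M
  af <- aggregator_forward(p$agg, cfg$agg, Zhat, train = train)
  cpc <- cpc_forward_backward(af$out, Zhat, p$heads, cfg$n_negatives,
                              want_grads = want_grads)
  breakdown <- list(cpc = cpc$total, codebook = d2,
                    commitment = cfg$gamma * d2,
                    total = cpc$total + d2 + cfg$gamma * d2,
                    per_k = cpc$per_k)
  if (!want_grads) return(list(breakdown = breakdown, indices = q$indices))
  w <- term_weights
  ab <- aggregator_backward(w[["cpc"]] * cpc$dC, p$agg, cfg$agg, af$caches)
  dZhat <- ab$dX + w[["cpc"]] * cpc$dZhat
  dZ <- dZhat +                                  # straight-through copy
    w[["commitment"]] * (2 * cfg$gamma / M) * diffZ
  eb <- encoder_backward(dZ, p$enc, cfg$enc, ef$caches)
  # codebook gradient: only from the codebook term
  Zm <- arr2mat(Z)
  idxm <- if (length(dim(q$indices)) == 3L) {
    matrix(aperm(q$indices, c(2L, 1L, 3L)), ncol = cfg$G)
  } else q$indices
  dcb <- vector("list", cfg$G)
  for (g in seq_len(cfg$G)) {
    sl <- ((g - 1L) * cb$dg + 1L):(g * cb$dg)
    E <- p$cb[[g]]
    contrib <- w[["codebook"]] * (2 / M) *
      (E[idxm[, g], , drop = FALSE] - Zm[, sl, drop = FALSE])
    dcb[[g]] <- scatter_add_rows(matrix(0, cb$V, cb$dg), idxm[, g], contrib)
  }
  grads <- list(enc = eb$grads, cb = dcb, agg = ab$grads,
                heads = lapply(cpc$dheads, function(h) w[["cpc"]] * h))
  list(breakdown = breakdown, grads = grads, indices = q$indices)
}

#' Evaluate the full training objective (Eq.-style breakdown)
#'
#' Runs encode -> quantize (straight-through) -> aggregate -> contrastive
#' future prediction and returns the three loss terms: the summed per-step
#' CPC losses, the codebook term and the gamma-weighted commitment term,
#' plus their total.
#'
#' @param model A [vqcpc_model()].
#' @param X Window batch (B x T x 3 array or single T x 3 matrix).
#' @param train If `TRUE`, dropout is active.
#' @param seed Optional seed for dropout/negative sampling; with a fixed
#'   seed the breakdown is bit-reproducible.
#' @return List with `cpc`, `codebook`, `commitment`, `total`, `per_k`.
#' @export
total_loss <- function(model, X, train = FALSE, seed = NULL) {
  run <- function() model_forward_backward(model, X, train = train,
                                           want_grads = FALSE)$breakdown
  if (is.null(seed)) run() else with_seed(seed, run())
}
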