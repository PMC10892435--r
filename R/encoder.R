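#' Convolutional encoder configuration
#'
#' The encoder maps a window of raw acceleration to a sequence of latent
#' z-vectors with four unpadded 1-D convolution blocks, each followed by
#' ReLU and dropout. The base architecture has channels (32, 64, 128, 256),
#' kernels (4, 1, 1, 1) and strides (2, 1, 1, 1): a 100-sample (2 s, 50 Hz)
#' window yields 49 z-vectors, i.e. an output frequency of 24.5 Hz, and each
#' z-vector sees 4 input samples (0.08 s).
#'
#' @param channels,kernels,strides Integer vectors, one entry per block.
#' @param dropout_p Dropout probability after each ReLU (default 0.2).
#' @param in_channels Number of input channels (default 3).
#' @return An `vqcpc_encoder_config`.
#' @export
encoder_config <- function(channels = c(32L, 64L, 128L, 256L),
                           kernels = c(4L, 1L, 1L, 1L),
                           strides = c(2L, 1L, 1L, 1L),
                           dropout_p = 0.2, in_channels = 3L) {
  stopifnot(length(channels) == length(kernels),
            length(kernels) == length(strides),
            all(kernels >= 1L), all(strides >= 1L))
  structure(list(channels = as.integer(channels),
                 kernels = as.integer(kernels),
                 strides = as.integer(strides),
                 dropout_p = dropout_p, in_channels = as.integer(in_channels)),
            class = "vqcpc_encoder_config")
}

#' Encoder output length for a given input length
#'
#' Applies the unpadded-convolution formula
#' `L <- floor((L - kernel) / stride) + 1` block by block.
#'
#' @param n_samples Input length in samples.
#' @param cfg An [encoder_config()].
#' @return Number of latent steps produced.
#' @export
output_length <- function(n_samples, cfg) {
  L <- as.integer(n_samples)
  for (i in seq_along(cfg$kernels)) {
    L <- conv1d_out_len(L, cfg$kernels[i], cfg$strides[i])
  }
  L
}

#' Encoder output frequency in Hz
#'
#' @param cfg An [encoder_config()].
#' @param input_hz Input sampling rate (default 50).
#' @param window_s Window duration in seconds (default 2).
#' @return Latent vectors per second.
#' @export
output_frequency <- function(cfg, input_hz = 50, window_s = 2) {
  output_length(as.integer(round(input_hz * window_s)), cfg) / window_s
}

#' Encoder receptive field in input samples
#'
#' `RF = 1 + sum_i (kernel_i - 1) * prod_{j<i} stride_j`: the number of
#' input timesteps that contribute to a single latent vector (4 for the
#' base configuration, i.e. 0.08 s at 50 Hz).
#'
#' @param cfg An [encoder_config()].
#' @return Receptive field in samples.
#' @export
receptive_field <- function(cfg) {
  rf <- 1L
  jump <- 1L
  for (i in seq_along(cfg$kernels)) {
    rf <- rf + (cfg$kernels[i] - 1L) * jump
    jump <- jump * cfg$strides[i]
  }
  rf
}

#' Named encoder variants controlling the output frequency
#'
#' Supported nominal targets for a 50 Hz / 2 s window: `24.5` (the base
#' configuration, unchanged), `50` (first block stride 1; second block
#' kernel and stride 1), and `11.5` (second block changed to kernel 4,
#' stride 2, halving the output rate again).
#'
#' @param cfg A base [encoder_config()].
#' @param target One of 24.5, 50, 11.5 (nominal Hz).
#' @return The modified configuration.
#' @export
encoder_variant <- function(cfg, target) {
  if (isTRUE(all.equal(target, 24.5))) {
    cfg
  } else if (isTRUE(all.equal(target, 50))) {
    cfg$strides[1L] <- 1L
    cfg$kernels[2L] <- 1L
    cfg$strides[2L] <- 1L
    cfg
  } else if (isTRUE(all.equal(target, 11.5))) {
    cfg$kernels[2L] <- 4L
    cfg$strides[2L] <- 2L
    cfg
  } else {
    stop_vqcpc(sprintf("unsupported output-frequency target %s", target),
               "vqcpc_config_error")
  }
}

#' Initialize encoder parameters
#'
#' Weights use fan-in-scaled uniform initialization
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; biases start at zero.
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed.
#' @return A parameter list (one `W`/`b` pair per block).
#' @export
init_encoder <- function(cfg, seed = 1L) {
  with_seed(seed, {
    cin <- cfg$in_channels
    params <- list()
    for (i in seq_along(cfg$channels)) {
      fan_in <- cfg$kernels[i] * cin
      bound <- 1 / sqrt(fan_in)
      params[[paste0("block", i)]] <- list(
        W = matrix(stats::runif(fan_in * cfg$channels[i], -bound, bound),
                   nrow = fan_in),
        b = numeric(cfg$channels[i]))
      cin <- cfg$channels[i]
    }
    params
  })
}

encoder_forward <- function(params, cfg, X, train = FALSE) {
  if (length(dim(X)) == 2L) X <- array(X, dim = c(1L, dim(X)))
  caches <- vector("list", length(cfg$kernels))
  H <- X
  for (i in seq_along(cfg$kernels)) {
    cv <- conv1d_forward(H, params[[i]]$W, params[[i]]$b,
                         cfg$kernels[i], cfg$strides[i])
    rl <- relu_forward(cv$out)
    dp <- dropout_forward(rl$out, cfg$dropout_p, train)
    caches[[i]] <- list(conv = cv$cache, relu = rl$mask, drop = dp$mask)
    H <- dp$out
  }
  list(out = H, caches = caches)
}

encoder_backward <- function(dZ, params, cfg, caches) {
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  dH <- dZ
  for (i in rev(seq_along(cfg$kernels))) {
    dH <- dropout_backward(dH, caches[[i]]$drop)
    dH <- dH * caches[[i]]$relu
    bw <- conv1d_backward(dH, caches[[i]]$conv)
    grads[[i]] <- list(W = bw$dW, b = bw$db)
    dH <- bw$dX
  }
  list(dX = dH, grads = grads)
}

#' Encode windows into latent z-vector sequences
#'
#' @param params Encoder parameters from [init_encoder()].
#' @param cfg The matching [encoder_config()].
#' @param X A single window (T x 3 matrix) or a batch array (B x T x 3).
#' @param train If `TRUE`, dropout is active (stochastic); in eval mode the
#'   mapping is a pure function.
#' @return Latent batch array (B x T' x d).
#' @export
encode <- function(params, cfg, X, train = FALSE) {
  encoder_forward(params, cfg, X, train = train)$out
}
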