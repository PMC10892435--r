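# Minimal neural-network primitives with explicit forward/backward passes.
#
# All sequence tensors are channel-last double arrays (batch, time, channels).
# Every forward returns the cached intermediates its backward needs; every
# backward returns gradients with the same shapes as its inputs/parameters.
# These are internal: the module-level functions (encoder, aggregator, ...)
# are the package surface.

# ---- 1-D convolution (valid, strided) --------------------------------------

conv1d_out_len <- function(len, kernel, stride) {
  if (len < kernel) {
    stop_vqcpc(sprintf("input length %d shorter than kernel %d", len, kernel),
               "vqcpc_input_too_short")
  }
  (len - kernel) %/% stride + 1L
}

# X: (B, T, Cin); W: (kernel*Cin) x Cout; b: length Cout
conv1d_forward <- function(X, W, b, kernel, stride) {
  d <- dim(X)
  B <- d[1]; Tt <- d[2]; Cin <- d[3]
  Tout <- conv1d_out_len(Tt, kernel, stride)
  Xm <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = Tt * B, ncol = Cin)
  base <- rep((0:(B - 1L)) * Tt, each = Tout) +
    rep((0:(Tout - 1L)) * stride, times = B)
  cols <- matrix(0, nrow = B * Tout, ncol = kernel * Cin)
  for (j in seq_len(kernel)) {
    cols[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xm[base + j, , drop = FALSE]
  }
  Ym <- cols %*% W
  Ym <- sweep(Ym, 2L, b, "+")
  Y <- aperm(array(Ym, dim = c(Tout, B, ncol(W))), c(2L, 1L, 3L))
  list(out = Y, cache = list(cols = cols, base = base, dimX = d,
                             kernel = kernel, stride = stride, W = W))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dimX
  B <- d[1]; Tt <- d[2]; Cin <- d[3]
  kernel <- cache$kernel
  Tout <- dim(dY)[2]
  dYm <- matrix(aperm(dY, c(2L, 1L, 3L)), nrow = Tout * B)
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dcols <- dYm %*% t(cache$W)
  dXm <- matrix(0, nrow = Tt * B, ncol = Cin)
  for (j in seq_len(kernel)) {
    idx <- cache$base + j
    dXm[idx, ] <- dXm[idx, , drop = FALSE] +
      dcols[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
  }
  dX <- aperm(array(dXm, dim = c(Tt, B, Cin)), c(2L, 1L, 3L))
  list(dX = dX, dW = dW, db = db)
}

# left-pad time axis with zeros (causal convolution support)
pad_left <- function(X, n) {
  if (n == 0L) return(X)
  d <- dim(X)
  P <- array(0, dim = c(d[1], d[2] + n, d[3]))
  P[, (n + 1L):(d[2] + n), ] <- X
  P
}

unpad_left_grad <- function(dXpad, n) {
  if (n == 0L) return(dXpad)
  d <- dim(dXpad)
  dXpad[, (n + 1L):d[2], , drop = FALSE]
}

# ---- pointwise ops ---------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

# inverted dropout; mask drawn from the current RNG stream
dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  keep <- array(stats::rbinom(length(X), 1L, 1 - p), dim = dim(X)) / (1 - p)
  list(out = X * keep, mask = keep)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- layer normalization (over last dim of a row-matrix) -------------------

layernorm_forward <- function(Xm, g, b, eps = 1e-5) {
  mu <- rowMeans(Xm)
  xc <- Xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  list(out = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# ---- batch normalization (per-feature, training/eval modes) ----------------

batchnorm_forward <- function(Xm, g, b, running, train, eps = 1e-5) {
  if (train) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    v <- colMeans(xc * xc)
    # cumulative moving average: stable for the short training runs used
    # at desk scale, equivalent to averaging all batch statistics seen
    running$n <- (running$n %||% 0) + 1
    mom <- 1 / running$n
    running$mean <- (1 - mom) * running$mean + mom * mu
    n <- nrow(Xm)
    vu <- if (n > 1) v * n / (n - 1) else v
    running$var <- (1 - mom) * running$var + mom * vu
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(Xm, 2L, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = y, running = running,
       cache = list(xhat = xhat, inv = inv, g = g, train = train))
}

batchnorm_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$g, "*")
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dX <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"),
                2L, cache$inv, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# ---- softmax cross-entropy -------------------------------------------------

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# logits: n x K, labels: integer in 1..K; returns mean loss and dlogits
# (already divided by n)
softmax_xent <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = P)
}

# ---- parameter trees and Adam ----------------------------------------------

# parameters are nested named lists with numeric-array leaves
tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    by_name <- !is.null(names(x)) && !is.null(names(y)) &&
      all(names(x) %in% names(y))
    for (i in seq_along(x)) {
      yi <- if (by_name) y[[names(x)[i]]] else y[[i]]
      out[[i]] <- tree_map2(f, x[[i]], yi)
    }
    out
  } else {
    f(x, y)
  }
}

tree_zeros_like <- function(x) tree_map(function(a) array(0, dim = dim(a) %||% length(a)), x)

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# classic Adam with L2 regularization folded into the gradient
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  }
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# accumulate rows of `contrib` into rows `idx` of matrix M (duplicates summed)
scatter_add_rows <- function(M, idx, contrib) {
  rs <- rowsum(contrib, group = idx)
  rows <- as.integer(rownames(rs))
  M[rows, ] <- M[rows, , drop = FALSE] + rs
  M
}
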