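# GRU and LSTM layers with masked batched BPTT. Gate layout follows the
# r/z/n (GRU) and i/f/g/o (LSTM) conventions; PAD positions (mask 0) leave
# the recurrent state untouched, so the final state is the state at the
# last real token of each sequence.

sigmoid <- function(x) 1 / (1 + exp(-x))

init_rnn_layer <- function(type, in_dim, hidden) {
  ng <- if (type == "gru") 3L else 4L
  bound <- 1 / sqrt(hidden)
  bx <- numeric(ng * hidden)
  # forget-gate bias starts at 1 so early LSTM training retains state
  if (type == "lstm") bx[(hidden + 1L):(2L * hidden)] <- 1
  list(Wx = matrix(stats::runif(in_dim * ng * hidden, -bound, bound),
                   nrow = in_dim),
       Wh = matrix(stats::runif(hidden * ng * hidden, -bound, bound),
                   nrow = hidden),
       bx = bx, bh = numeric(ng * hidden))
}

gru_forward <- function(p, X, mask) {
  B <- dim(X)[1]; L <- dim(X)[2]
  H <- ncol(p$Wh) %/% 3L
  h <- matrix(0, B, H)
  out <- array(0, dim = c(B, L, H))
  caches <- vector("list", L)
  ir <- 1:H; iz <- (H + 1L):(2L * H); inn <- (2L * H + 1L):(3L * H)
  for (t in seq_len(L)) {
    x <- matrix(X[, t, ], nrow = B)
    m <- mask[, t]
    gx <- sweep(x %*% p$Wx, 2L, p$bx, "+")
    gh <- sweep(h %*% p$Wh, 2L, p$bh, "+")
    r <- sigmoid(gx[, ir] + gh[, ir])
    z <- sigmoid(gx[, iz] + gh[, iz])
    n <- tanh(gx[, inn] + r * gh[, inn])
    hnew <- (1 - z) * n + z * h
    hmask <- m * hnew + (1 - m) * h
    caches[[t]] <- list(x = x, hprev = h, r = r, z = z, n = n,
                        ghn = gh[, inn], m = m)
    h <- hmask
    out[, t, ] <- h
  }
  list(out = out, h_final = h, caches = caches)
}

gru_backward <- function(p, caches, dOut, dHfinal) {
  L <- length(caches)
  B <- nrow(caches[[1]]$x)
  H <- length(p$bx) %/% 3L
  ir <- 1:H; iz <- (H + 1L):(2L * H); inn <- (2L * H + 1L):(3L * H)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  dbx <- numeric(3L * H); dbh <- numeric(3L * H)
  dX <- array(0, dim = c(B, L, nrow(p$Wx)))
  dh <- dHfinal
  for (t in rev(seq_len(L))) {
    ca <- caches[[t]]
    dh <- dh + matrix(dOut[, t, ], nrow = B)
    dhnew <- ca$m * dh
    dhprev <- (1 - ca$m) * dh
    dz <- dhnew * (ca$hprev - ca$n)
    dn <- dhnew * (1 - ca$z)
    dhprev <- dhprev + dhnew * ca$z
    dn_pre <- dn * (1 - ca$n^2)
    dr <- dn_pre * ca$ghn
    dr_pre <- dr * ca$r * (1 - ca$r)
    dz_pre <- dz * ca$z * (1 - ca$z)
    dgx <- cbind(dr_pre, dz_pre, dn_pre)
    dgh <- cbind(dr_pre, dz_pre, dn_pre * ca$r)
    dWx <- dWx + crossprod(ca$x, dgx)
    dbx <- dbx + colSums(dgx)
    dWh <- dWh + crossprod(ca$hprev, dgh)
    dbh <- dbh + colSums(dgh)
    dX[, t, ] <- dgx %*% t(p$Wx)
    dh <- dhprev + dgh %*% t(p$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh), dX = dX)
}

lstm_forward <- function(p, X, mask) {
  B <- dim(X)[1]; L <- dim(X)[2]
  H <- length(p$bx) %/% 4L
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, dim = c(B, L, H))
  caches <- vector("list", L)
  ii <- 1:H; jf <- (H + 1L):(2L * H); jg <- (2L * H + 1L):(3L * H)
  jo <- (3L * H + 1L):(4L * H)
  for (t in seq_len(L)) {
    x <- matrix(X[, t, ], nrow = B)
    m <- mask[, t]
    a <- sweep(x %*% p$Wx, 2L, p$bx, "+") + sweep(h %*% p$Wh, 2L, p$bh, "+")
    i <- sigmoid(a[, ii]); f <- sigmoid(a[, jf])
    g <- tanh(a[, jg]); o <- sigmoid(a[, jo])
    cnew <- f * cc + i * g
    tc <- tanh(cnew)
    hnew <- o * tc
    caches[[t]] <- list(x = x, hprev = h, cprev = cc, i = i, f = f, g = g,
                        o = o, tc = tc, m = m)
    h <- m * hnew + (1 - m) * h
    cc <- m * cnew + (1 - m) * cc
    out[, t, ] <- h
  }
  list(out = out, h_final = h, caches = caches)
}

lstm_backward <- function(p, caches, dOut, dHfinal) {
  L <- length(caches)
  B <- nrow(caches[[1]]$x)
  H <- length(p$bx) %/% 4L
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  dbx <- numeric(4L * H); dbh <- numeric(4L * H)
  dX <- array(0, dim = c(B, L, nrow(p$Wx)))
  dh <- dHfinal
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    ca <- caches[[t]]
    dh <- dh + matrix(dOut[, t, ], nrow = B)
    dhnew <- ca$m * dh
    dhprev <- (1 - ca$m) * dh
    dcnew <- ca$m * dc
    dcprev <- (1 - ca$m) * dc
    do_ <- dhnew * ca$tc
    dcnew <- dcnew + dhnew * ca$o * (1 - ca$tc^2)
    df <- dcnew * ca$cprev
    di <- dcnew * ca$g
    dg <- dcnew * ca$i
    dcprev <- dcprev + dcnew * ca$f
    da <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2), do_ * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$x, da)
    dbx <- dbx + colSums(da)
    dWh <- dWh + crossprod(ca$hprev, da)
    dbh <- dbh + colSums(da)
    dX[, t, ] <- da %*% t(p$Wx)
    dh <- dhprev + da %*% t(p$Wh)
    dc <- dcprev
  }
  list(grads = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh), dX = dX)
}
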