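#' Initialize a grouped codebook
#'
#' The d-dimensional latent space is split into `G` contiguous groups of
#' `d/G` dimensions; each group has its own table of `V` learnable vectors.
#' Entries are drawn i.i.d. uniform on `(-1/sqrt(d/G), 1/sqrt(d/G))`.
#' Defaults follow the pre-training setup (G = 2, V = 100, gamma = 0.25);
#' the constrained-alphabet mode uses G = 1 with V in {32, ..., 512}.
#'
#' @param G Number of groups.
#' @param V Codebook vectors per group.
#' @param d Full latent dimensionality (must be divisible by `G`).
#' @param seed Integer seed.
#' @param gamma Commitment-loss weight (default 0.25).
#' @return A `vqcpc_codebook` with a `V x d/G` matrix per group.
#' @export
init_codebook <- function(G, V, d, seed = 1L, gamma = 0.25) {
  if (d %% G != 0L) {
    stop_vqcpc(sprintf("latent dim %d not divisible by %d groups", d, G),
               "vqcpc_config_error")
  }
  dg <- d %/% G
  bound <- 1 / sqrt(dg)
  vectors <- with_seed(seed, {
    lapply(seq_len(G), function(g) {
      matrix(stats::runif(V * dg, -bound, bound), nrow = V)
    })
  })
  structure(list(G = as.integer(G), V = as.integer(V), d = as.integer(d),
                 dg = as.integer(dg), gamma = gamma, vectors = vectors),
            class = "vqcpc_codebook")
}

# squared Euclidean distances between rows of Z (M x dg) and rows of E (V x dg)
sq_dists <- function(Z, E) {
  outer(rowSums(Z * Z), rep(1, nrow(E))) +
    outer(rep(1, nrow(Z)), rowSums(E * E)) - 2 * Z %*% t(E)
}

#' Quantize latent vectors to their nearest codebook rows
#'
#' Each latent vector is split into the codebook's `G` contiguous slices;
#' per slice the nearest codebook row under squared Euclidean distance is
#' selected (ties broken by lowest index) and substituted, so each group
#' slice of the output equals a codebook row exactly.
#'
#' @param Z Latent batch (B x T' x d array) or matrix (M x d).
#' @param cb A [init_codebook()] codebook.
#' @return A list with `z_hat` (same shape as `Z`) and `indices`
#'   (B x T' x G array or M x G matrix of 1-based codeword indices).
#' @export
quantize <- function(Z, cb) {
  dims <- dim(Z)
  flat <- length(dims) == 2L
  Zm <- if (flat) Z else matrix(aperm(Z, c(2L, 1L, 3L)), ncol = dims[3])
  if (ncol(Zm) != cb$d) {
    stop_vqcpc(sprintf("latent dim %d does not match codebook dim %d",
                       ncol(Zm), cb$d), "vqcpc_config_error")
  }
  M <- nrow(Zm)
  z_hat <- matrix(0, M, cb$d)
  idx <- matrix(0L, M, cb$G)
  for (g in seq_len(cb$G)) {
    sl <- ((g - 1L) * cb$dg + 1L):(g * cb$dg)
    D <- sq_dists(Zm[, sl, drop = FALSE], cb$vectors[[g]])
    ig <- max.col(-D, ties.method = "first")
    idx[, g] <- ig
    z_hat[, sl] <- cb$vectors[[g]][ig, , drop = FALSE]
  }
  if (!flat) {
    z_hat <- aperm(array(z_hat, dim = c(dims[2], dims[1], dims[3])),
                   c(2L, 1L, 3L))
    idx <- aperm(array(idx, dim = c(dims[2], dims[1], cb$G)), c(2L, 1L, 3L))
  }
  list(z_hat = z_hat, indices = idx)
}

#' Codebook and commitment losses
#'
#' The codebook term `||sg(z) - z_hat||^2` pulls codewords toward encoder
#' outputs (its gradient reaches only the codebook); the commitment term
#' `gamma * ||z - sg(z_hat)||^2` pulls encoder outputs toward their chosen
#' codewords (its gradient reaches only the encoder). Both are the squared
#' Euclidean norm per vector, averaged over batch items and timesteps.
#'
#' @param z,z_hat Arrays/matrices of matching shape.
#' @param gamma Commitment weight.
#' @return Named numeric vector `c(codebook =, commitment =)`.
#' @export
vq_losses <- function(z, z_hat, gamma = 0.25) {
  dims <- dim(z)
  n_vec <- if (length(dims) == 3L) dims[1] * dims[2] else nrow(as.matrix(z))
  d2 <- sum((z - z_hat)^2) / n_vec
  c(codebook = d2, commitment = gamma * d2)
}

#' Straight-through estimator
#'
#' Forward value is the quantized `z_hat`; during backpropagation the
#' gradient of any downstream loss with respect to `z` is copied
#' element-wise from its gradient with respect to `z_hat` (equivalently,
#' the op computes `z + sg(z_hat - z)`). The training routines implement
#' this routing explicitly; this helper exposes the forward value.
#'
#' @param z Encoder output.
#' @param z_hat Quantized replacement of matching shape.
#' @return `z_hat` (identical value, as passed to the aggregator).
#' @export
straight_through <- function(z, z_hat) {
  stopifnot(identical(dim(z), dim(z_hat)))
  z + (z_hat - z)
}

#' Codebook-usage diagnostics
#'
#' Per-group usage histograms, usage perplexity `exp(entropy)` (V when all
#' codes are used uniformly, 1 under complete mode collapse), and the number
#' of distinct joint G-tuples observed — the effective alphabet, typically
#' far below `V^G`.
#'
#' @param indices Integer indices from [quantize()] (matrix M x G or array
#'   N x T' x G).
#' @param V Codebook size per group.
#' @return List with `histograms` (G x V matrix of frequencies),
#'   `perplexity` (length-G vector), and `joint_size` (scalar count).
#' @export
codebook_stats <- function(indices, V) {
  if (length(dim(indices)) == 3L) {
    d <- dim(indices)
    indices <- matrix(aperm(indices, c(2L, 1L, 3L)), ncol = d[3])
  }
  indices <- as.matrix(indices)
  G <- ncol(indices)
  hist <- matrix(0, G, V)
  perp <- numeric(G)
  for (g in seq_len(G)) {
    counts <- tabulate(indices[, g], nbins = V)
    p <- counts / sum(counts)
    hist[g, ] <- p
    nz <- p[p > 0]
    perp[g] <- exp(-sum(nz * log(nz)))
  }
  joint <- nrow(unique(indices))
  list(histograms = hist, perplexity = perp, joint_size = joint)
}
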