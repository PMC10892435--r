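# small deterministic building blocks used across test files

tiny_model <- function(seed = 7L, G = 2L, V = 5L, K = 2L, N = 3L,
                       dropout = 0) {
  ecfg <- encoder_config(channels = c(4L, 6L), kernels = c(3L, 2L),
                         strides = c(2L, 1L), dropout_p = dropout)
  m <- vqcpc_model(ecfg, n_agg_blocks = 2L, G = G, V = V, K = K,
                   n_negatives = N, seed = seed)
  m$cfg$agg$dropout_p <- dropout
  m
}

random_batch <- function(B = 2L, Tt = 20L, seed = 1L) {
  with_seed(seed, array(stats::rnorm(B * Tt * 3L), dim = c(B, Tt, 3L)))
}

# flatten a model-gradient tree into a single named numeric vector
flatten_tree <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- numeric(0)
    for (nm in names(x) %||% seq_along(x)) {
      out <- c(out, flatten_tree(x[[nm]], paste0(prefix, ".", nm)))
    }
    out
  } else {
    v <- as.numeric(x)
    names(v) <- paste0(prefix, "[", seq_along(v), "]")
    v
  }
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
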