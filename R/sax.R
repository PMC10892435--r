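#' SAX configuration
#'
#' Symbolic Aggregate approXimation on the acceleration magnitude: one
#' symbol for every second timestep of a 100-sample window (50 symbols) with
#' an alphabet of 512, matching the resolution of the learned discretizer.
#'
#' @param alphabet_size Alphabet size a (>= 2; default 512).
#' @param symbols_per_window Symbols per window (must divide the window
#'   length; default 50).
#' @param per_window_znorm Z-normalize each window's magnitude before PAA
#'   (default TRUE; without it the Gaussian breakpoints are meaningless).
#' @return A `vqcpc_sax_config`.
#' @export
sax_config <- function(alphabet_size = 512L, symbols_per_window = 50L,
                       per_window_znorm = TRUE) {
  stopifnot(alphabet_size >= 2L)
  structure(list(alphabet_size = as.integer(alphabet_size),
                 symbols_per_window = as.integer(symbols_per_window),
                 per_window_znorm = per_window_znorm),
            class = "vqcpc_sax_config")
}

#' Equiprobable standard-normal breakpoints
#'
#' The a-1 thresholds that cut the standard normal into a equal-probability
#' bins: `qnorm(i/a)` for i = 1..a-1.
#'
#' @param a Alphabet size (>= 2).
#' @return Numeric vector of a-1 thresholds.
#' @export
gaussian_breakpoints <- function(a) {
  stopifnot(a >= 2L)
  stats::qnorm(seq_len(a - 1L) / a)
}

#' Piecewise Aggregate Approximation
#'
#' Mean of each of `n_segments` equal contiguous segments; `n_segments`
#' must divide the series length.
#'
#' @param series Numeric vector.
#' @param n_segments Number of segments.
#' @return Numeric vector of segment means.
#' @export
paa <- function(series, n_segments) {
  n <- length(series)
  if (n %% n_segments != 0L) {
    stop_vqcpc(sprintf("%d segments do not divide series length %d",
                       n_segments, n), "vqcpc_config_error")
  }
  colMeans(matrix(series, nrow = n %/% n_segments))
}

sax_symbolize <- function(series, cfg) {
  if (cfg$per_window_znorm) {
    s <- stats::sd(series)
    series <- if (s > 0) (series - mean(series)) / s else series - mean(series)
  }
  means <- paa(series, cfg$symbols_per_window)
  findInterval(means, gaussian_breakpoints(cfg$alphabet_size))  # 0..a-1
}

#' SAX transform of a sensor window
#'
#' The triaxial window is reduced to its per-sample magnitude
#' `sqrt(x^2 + y^2 + z^2)`, z-normalized per window, mean-pooled by PAA and
#' binned by the equiprobable Gaussian breakpoints, giving integer symbols
#' in `0..a-1`. A zero-variance magnitude yields the middle bin throughout.
#'
#' @param window A sensor window (or plain T x 3 matrix).
#' @param cfg A [sax_config()].
#' @return Integer symbol vector of length `symbols_per_window`.
#' @export
sax_transform <- function(window, cfg = sax_config()) {
  V <- if (inherits(window, "vqcpc_window")) window$values else window
  magnitude <- sqrt(rowSums(V^2))
  sax_symbolize(magnitude, cfg)
}

#' SAX token corpus for a list of windows
#'
#' Produces tuple-string sequences in the same corpus format as
#' [discretize()], so the downstream classifier is reused unchanged.
#'
#' @param windows List of sensor windows.
#' @param cfg A [sax_config()].
#' @return List of character vectors with `label`/`subject` attributes.
#' @export
sax_corpus <- function(windows, cfg = sax_config()) {
  seqs <- lapply(windows, function(w) as.character(sax_transform(w, cfg)))
  attr(seqs, "label") <- window_labels(windows)
  attr(seqs, "subject") <- window_subjects(windows)
  seqs
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    dn <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  centers
}

#' SAX-REPEAT transform for multi-channel windows
#'
#' Applies SAX per channel (alphabet `cfg$alphabet_size` each), forms the
#' per-position 3-tuples of symbol indices, and clusters the training-split
#' tuples with K-means (k = 512 by default, k-means++ seeding with 10
#' restarts, refined by Lloyd iterations) so the final alphabet stays at k.
#' Evaluation tuples are assigned to their nearest centroid.
#'
#' @param train_windows,eval_windows Lists of sensor windows; centroids are
#'   fitted on `train_windows` only.
#' @param cfg A [sax_config()] used per channel.
#' @param k Number of clusters (reduced with a warning if the training set
#'   has fewer distinct tuples).
#' @param seed Integer seed.
#' @return List with `train` and `eval` tuple-string corpora (cluster
#'   indices, 0-based) and the fitted `centers`.
#' @export
sax_repeat_transform <- function(train_windows, eval_windows = list(),
                                 cfg = sax_config(), k = 512L, seed = 1L) {
  if (!length(train_windows)) {
    stop_vqcpc("empty training set", "vqcpc_config_error")
  }
  channel_tuples <- function(windows) {
    lapply(windows, function(w) {
      V <- if (inherits(w, "vqcpc_window")) w$values else w
      sapply(1:3, function(ch) sax_symbolize(V[, ch], cfg))  # S x 3
    })
  }
  tr <- channel_tuples(train_windows)
  ev <- channel_tuples(eval_windows)
  Xtr <- do.call(rbind, tr)
  n_distinct <- nrow(unique(Xtr))
  if (k > n_distinct) {
    warning(sprintf("reducing k from %d to %d distinct training tuples",
                    k, n_distinct))
    k <- n_distinct
  }
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(10L)) {
      centers <- kmeanspp_centers(Xtr, k)
      centers <- unique(centers)
      km <- suppressWarnings(
        stats::kmeans(Xtr, centers = centers, iter.max = 50L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  assign_tuples <- function(tuple_list) {
    lapply(tuple_list, function(M) {
      D <- sq_dists(M, fit$centers)
      as.character(max.col(-D, ties.method = "first") - 1L)
    })
  }
  out_tr <- assign_tuples(tr)
  attr(out_tr, "label") <- window_labels(train_windows)
  attr(out_tr, "subject") <- window_subjects(train_windows)
  out_ev <- assign_tuples(ev)
  if (length(eval_windows)) {
    attr(out_ev, "label") <- window_labels(eval_windows)
    attr(out_ev, "subject") <- window_subjects(eval_windows)
  }
  list(train = out_tr, eval = out_ev, centers = fit$centers)
}
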