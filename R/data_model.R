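#' Recording and window handling for triaxial accelerometer data
#'
#' A *recording* is one subject's continuous stream of triaxial acceleration
#' (in g) with per-sample timestamps and optional per-sample activity labels.
#' All downstream processing operates on fixed-length *windows* (2 s at
#' 50 Hz, i.e. 100 samples) cut from recordings.
#'
#' @param subject_id Character subject identifier.
#' @param samples Numeric matrix, samples x 3 (channels x, y, z, in g).
#' @param rate_hz Sampling rate in Hz.
#' @param timestamps Numeric vector of seconds, strictly increasing; defaults
#'   to a regular grid at `rate_hz`.
#' @param labels Optional character vector of per-sample activity labels.
#' @return An object of class `vqcpc_recording`.
#' @export
new_recording <- function(subject_id, samples, rate_hz,
                          timestamps = NULL, labels = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) {
    stop_vqcpc("recordings must have exactly 3 channels (x, y, z)",
               "vqcpc_format_error")
  }
  n <- nrow(samples)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / rate_hz
  if (length(timestamps) != n || any(diff(timestamps) <= 0)) {
    stop_vqcpc("timestamps must be strictly increasing and match samples",
               "vqcpc_data_error")
  }
  if (!is.null(labels) && length(labels) != n) {
    stop_vqcpc("labels must have one entry per sample", "vqcpc_data_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 timestamps = as.numeric(timestamps),
                 samples = unname(samples),
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 rate_hz = rate_hz),
            class = "vqcpc_recording")
}

#' @export
print.vqcpc_recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, nrow(x$samples), x$rate_hz,
              nrow(x$samples) / x$rate_hz,
              if (is.null(x$labels)) "" else
                sprintf(", %d labels", length(unique(x$labels)))))
  invisible(x)
}

#' Read recordings from a CSV file
#'
#' The expected dialect has a header `subject,timestamp,x,y,z` with an
#' optional trailing `label` column; rows may interleave subjects. One
#' recording per subject is returned, in order of first appearance.
#'
#' @param path Path to a CSV file.
#' @param rate_hz Sampling rate; if `NULL`, inferred per subject as the
#'   reciprocal of the median timestamp increment.
#' @return A list of [new_recording()] objects, one per subject.
#' @export
read_recording <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "timestamp", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_vqcpc(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
               "vqcpc_format_error")
  }
  has_label <- "label" %in% names(df)
  subjects <- unique(df$subject)
  lapply(subjects, function(s) {
    sub <- df[df$subject == s, , drop = FALSE]
    ts <- sub$timestamp
    if (any(diff(ts) <= 0)) {
      stop_vqcpc(sprintf("non-monotone timestamps for subject %s", s),
                 "vqcpc_data_error")
    }
    rate <- rate_hz %||% (1 / stats::median(diff(ts)))
    new_recording(subject_id = s,
                  samples = cbind(sub$x, sub$y, sub$z),
                  rate_hz = rate, timestamps = ts,
                  labels = if (has_label) sub$label else NULL)
  })
}

#' Write recordings to the CSV dialect read by [read_recording()]
#'
#' @param recordings A list of recordings (or a single recording).
#' @param path Output CSV path.
#' @export
write_recordings <- function(recordings, path) {
  if (inherits(recordings, "vqcpc_recording")) recordings <- list(recordings)
  dfs <- lapply(recordings, function(r) {
    df <- data.frame(subject = r$subject_id, timestamp = r$timestamps,
                     x = r$samples[, 1], y = r$samples[, 2],
                     z = r$samples[, 3])
    if (!is.null(r$labels)) df$label <- r$labels
    df
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Reduce a recording's sampling rate by integer decimation
#'
#' Sub-sampling keeps every k-th sample (k = `rate_hz / target_hz`); labels
#' and timestamps are decimated identically. No anti-alias filter is applied.
#'
#' @param rec A recording.
#' @param target_hz Target rate; must divide the current rate.
#' @return The decimated recording.
#' @export
resample_recording <- function(rec, target_hz) {
  ratio <- rec$rate_hz / target_hz
  if (ratio < 1 || abs(ratio - round(ratio)) > 1e-9) {
    stop_vqcpc(sprintf("cannot sub-sample %g Hz to %g Hz (non-integer ratio)",
                       rec$rate_hz, target_hz), "vqcpc_unsupported_rate")
  }
  k <- as.integer(round(ratio))
  if (k == 1L) return(rec)
  keep <- seq(1L, nrow(rec$samples), by = k)
  new_recording(rec$subject_id, rec$samples[keep, , drop = FALSE], target_hz,
                timestamps = rec$timestamps[keep],
                labels = if (is.null(rec$labels)) NULL else rec$labels[keep])
}

majority_label <- function(labels) {
  # modal label; ties broken by first appearance within the window
  tab <- table(factor(labels, levels = unique(labels)))
  names(tab)[which.max(tab)]
}

#' Cut a recording into fixed-length windows
#'
#' Windows are `window_s` seconds long (100 samples at 50 Hz) with stride
#' `T * (1 - overlap_frac)` samples; a trailing partial window is dropped.
#' Start offsets are 0-based and windows are half-open `[start, start + T)`.
#' The window label is the majority vote over per-sample labels (ties broken
#' by first-seen label).
#'
#' @param rec A recording.
#' @param window_s Window length in seconds (default 2).
#' @param overlap_frac Fractional overlap in `[0, 1)` (default 0).
#' @return A list of `vqcpc_window` objects (possibly empty).
#' @export
make_windows <- function(rec, window_s = 2, overlap_frac = 0) {
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop_vqcpc("overlap_frac must be in [0, 1)", "vqcpc_config_error")
  }
  Tw <- as.integer(round(rec$rate_hz * window_s))
  stride <- as.integer(round(Tw * (1 - overlap_frac)))
  n <- nrow(rec$samples)
  if (n < Tw) return(list())
  starts <- seq(0L, n - Tw, by = stride)
  lapply(starts, function(s) {
    idx <- (s + 1L):(s + Tw)
    structure(list(values = rec$samples[idx, , drop = FALSE],
                   subject_id = rec$subject_id,
                   label = if (is.null(rec$labels)) NULL else
                     majority_label(rec$labels[idx]),
                   start_index = s),
              class = "vqcpc_window")
  })
}

windows_to_array <- function(windows) {
  Tw <- nrow(windows[[1]]$values)
  X <- array(0, dim = c(length(windows), Tw, 3L))
  for (i in seq_along(windows)) X[i, , ] <- windows[[i]]$values
  X
}

window_labels <- function(windows) {
  vapply(windows, function(w) {
    if (inherits(w, "vqcpc_window")) w$label %||% NA_character_
    else NA_character_
  }, character(1))
}

window_subjects <- function(windows) {
  vapply(windows, function(w) {
    if (inherits(w, "vqcpc_window")) w$subject_id else NA_character_
  }, character(1))
}

#' Fit and apply per-channel z-scoring
#'
#' Normalization statistics are fitted once on the pre-training train split
#' and reused verbatim for every other split (validation, test, downstream
#' datasets), so no information leaks across splits.
#'
#' @param windows A list of windows (the train split for fitting).
#' @return `fit_normalization`: a list with per-channel `mean` and `std`.
#' @export
fit_normalization <- function(windows) {
  if (!length(windows)) stop_vqcpc("empty train split", "vqcpc_config_error")
  M <- do.call(rbind, lapply(windows, function(w) w$values))
  mean <- colMeans(M)
  std <- apply(M, 2L, stats::sd)
  if (any(std <= 0)) {
    stop_vqcpc("zero-variance channel in train split", "vqcpc_degenerate_data")
  }
  list(mean = mean, std = std)
}

#' @rdname fit_normalization
#' @param stats Statistics from `fit_normalization`.
#' @export
apply_normalization <- function(windows, stats) {
  lapply(windows, function(w) {
    w$values <- sweep(sweep(w$values, 2L, stats$mean), 2L, stats$std, "/")
    w
  })
}

#' Invert per-channel z-scoring (round-trip support)
#' @rdname fit_normalization
#' @export
invert_normalization <- function(windows, stats) {
  lapply(windows, function(w) {
    w$values <- sweep(sweep(w$values, 2L, stats$std, "*"), 2L, stats$mean, "+")
    w
  })
}

#' Participant-wise five-fold splits
#'
#' Fold 1 splits the subjects 80:20 into train-val and test; train-val is
#' re-split 80:20 into train and validation. Each later fold takes a fresh
#' ~20% of subjects as its test set, disjoint from every previous test set,
#' and splits the remaining subjects 80:20 into train/validation. Test sets
#' therefore partition the subject pool (sizes differing by at most one when
#' the count is not divisible by the number of folds).
#'
#' @param subjects Character vector of subject ids (at least `n_folds`).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the shuffling.
#' @return A list of folds, each a list with `fold_id`, `train`, `val`,
#'   `test` subject-id vectors.
#' @export
make_participant_folds <- function(subjects, n_folds = 5L, seed = 1L) {
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  if (n < n_folds) {
    stop_vqcpc(sprintf("%d subjects cannot form %d folds", n, n_folds),
               "vqcpc_config_error")
  }
  with_seed(seed, {
    shuffled <- sample(subjects)
    sizes <- rep(n %/% n_folds, n_folds)
    extra <- n %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    test_sets <- lapply(seq_len(n_folds),
                        function(i) shuffled[starts[i]:ends[i]])
    lapply(seq_len(n_folds), function(i) {
      rest <- sample(setdiff(shuffled, test_sets[[i]]))
      n_val <- max(1L, round(0.2 * length(rest)))
      list(fold_id = i,
           train = sort(rest[(n_val + 1L):length(rest)]),
           val = sort(rest[seq_len(n_val)]),
           test = sort(test_sets[[i]]))
    })
  })
}
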