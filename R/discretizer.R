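tuple_strings <- function(idx_mat) {
  apply(idx_mat, 1L, function(r) paste(r, collapse = "-"))
}

#' Discretize windows into per-window codeword tuple sequences
#'
#' Inference path: encoder then quantizer, in eval mode (the aggregator is
#' not used at inference). Each window becomes a sequence of T' G-tuples of
#' codebook indices, serialized as strings `"i1-i2"`.
#'
#' @param model A (typically pre-trained) [vqcpc_model()].
#' @param windows A list of normalized windows.
#' @return A list (one element per window) of character vectors of tuples,
#'   with attributes carrying the window labels and subjects.
#' @export
discretize <- function(model, windows) {
  X <- windows_to_array(windows)
  Z <- encode(model$params$enc, model$cfg$enc, X, train = FALSE)
  q <- quantize(Z, model_codebook(model))
  seqs <- lapply(seq_len(dim(X)[1]), function(i) {
    tuple_strings(matrix(q$indices[i, , ], ncol = model$cfg$G))
  })
  attr(seqs, "label") <- window_labels(windows)
  attr(seqs, "subject") <- window_subjects(windows)
  seqs
}

SPECIALS <- c(PAD = 0L, UNK = 1L, START = 2L, END = 3L)

#' Build the token vocabulary from training-split sequences
#'
#' Special tokens occupy fixed ids (PAD = 0, UNK = 1, START = 2, END = 3);
#' every distinct tuple observed in the training split gets the next id in
#' first-occurrence order. Tuples seen only at validation/test time map to
#' UNK. The vocabulary must be built from the training split only.
#'
#' @param train_sequences List of tuple-string vectors from [discretize()].
#' @return A `vqcpc_vocabulary` with `map` (named integer vector) and `size`.
#' @export
build_vocabulary <- function(train_sequences) {
  if (!length(train_sequences)) {
    stop_vqcpc("cannot build a vocabulary from an empty corpus",
               "vqcpc_config_error")
  }
  tuples <- unique(unlist(train_sequences, use.names = FALSE))
  map <- seq_along(tuples) + 3L
  names(map) <- tuples
  structure(list(specials = SPECIALS, map = map,
                 size = length(map) + length(SPECIALS)),
            class = "vqcpc_vocabulary")
}

#' @export
print.vqcpc_vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (%d tuples + 4 specials)\n",
              x$size, length(x$map)))
  invisible(x)
}

#' Encode a tuple sequence as token ids
#'
#' Prepends START and appends END; unseen tuples become UNK.
#'
#' @param tuples Character vector of tuples.
#' @param vocab A [build_vocabulary()] vocabulary.
#' @return Integer id vector of length `length(tuples) + 2`.
#' @export
encode_sequence <- function(tuples, vocab) {
  ids <- unname(vocab$map[tuples])
  ids[is.na(ids)] <- SPECIALS[["UNK"]]
  c(SPECIALS[["START"]], ids, SPECIALS[["END"]])
}

#' Decode token ids back to tuples (round-trip support)
#'
#' @param ids Integer id vector (START/END/PAD stripped; UNK becomes NA).
#' @param vocab The vocabulary.
#' @return Character vector of tuples.
#' @export
decode_sequence <- function(ids, vocab) {
  inv <- names(vocab$map)
  ids <- ids[!(ids %in% SPECIALS[c("PAD", "START", "END")])]
  out <- rep(NA_character_, length(ids))
  real <- ids >= 4L
  out[real] <- inv[ids[real] - 3L]
  out
}

#' Pad encoded sequences to a common length
#'
#' @param sequences List of id vectors from [encode_sequence()].
#' @param length_out Target length (default: longest sequence).
#' @return List with `ids` (n x length_out integer matrix, PAD-filled) and
#'   `mask` (same shape, 1 for real tokens).
#' @export
pad_batch <- function(sequences, length_out = NULL) {
  lens <- lengths(sequences)
  L <- length_out %||% max(lens)
  if (any(lens > L)) {
    stop_vqcpc("a sequence is longer than the padding length",
               "vqcpc_config_error")
  }
  ids <- matrix(SPECIALS[["PAD"]], length(sequences), L)
  mask <- matrix(0, length(sequences), L)
  for (i in seq_along(sequences)) {
    ids[i, seq_len(lens[i])] <- sequences[[i]]
    mask[i, seq_len(lens[i])] <- 1
  }
  list(ids = ids, mask = mask)
}

#' Per-activity symbol usage histograms
#'
#' For each activity, the fraction of symbol occurrences held by each token
#' (special tokens excluded); fractions sum to one per activity. Low-motion
#' activities concentrate on a handful of symbols while dynamic ones spread
#' across many.
#'
#' @param sequences List of tuple-string vectors (or id vectors).
#' @param labels Activity label per sequence (default: the `label`
#'   attribute attached by [discretize()]).
#' @return A data.frame with columns `activity`, `token`, `fraction`.
#' @export
symbol_histograms <- function(sequences, labels = attr(sequences, "label")) {
  stopifnot(length(labels) == length(sequences))
  out <- NULL
  for (act in unique(labels)) {
    toks <- unlist(sequences[labels == act], use.names = FALSE)
    tab <- table(toks)
    out <- rbind(out, data.frame(activity = act, token = names(tab),
                                 fraction = as.numeric(tab) / length(toks)))
  }
  rownames(out) <- NULL
  out
}

#' Write/read a token corpus as plain text (one window per line)
#'
#' @param sequences List of tuple-string vectors.
#' @param path Output path.
#' @export
write_token_corpus <- function(sequences, path) {
  writeLines(vapply(sequences, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' @rdname write_token_corpus
#' @export
read_token_corpus <- function(path) {
  lapply(strsplit(readLines(path), " ", fixed = TRUE), identity)
}
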