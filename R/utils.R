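#' Derive a per-stage seed from a global seed
#'
#' Pipeline stages each receive their own RNG seed so that any stage can be
#' re-run in isolation and reproduce its part of a full run. The derivation
#' is a fixed integer hash of the global seed and a stage label, reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. "synth", "pretrain").
#' @param k Optional integer counter for stages that need several streams.
#' @return A single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.double(seed) * 48271 + h * 16807 + as.double(k) * 69621) %% 2147483646
  as.integer(x) + 1L
}

# run expr with a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_vqcpc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vqcpc_error")))
}
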