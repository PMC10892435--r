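#' Specify one synthetic activity regime
#'
#' Synthetic wrist accelerometry is modelled per activity as a static gravity
#' offset plus a sum of sinusoidal harmonics plus i.i.d. Gaussian sensor
#' noise. Harmonic amplitudes are scaled by a per-subject log-normal gain and
#' phases are jittered per subject, so subjects differ systematically and
#' participant-wise folds are non-trivial.
#'
#' @param name Activity label.
#' @param gravity Length-3 static offset in g.
#' @param harmonics List of harmonics, each `list(freq, amp, phase)`, with
#'   `freq` in Hz (must stay below the 25 Hz Nyquist limit at 50 Hz),
#'   `amp` a length-3 per-channel amplitude in g, `phase` in radians.
#' @param noise_sd Gaussian noise standard deviation in g (>= 0).
#' @return An `vqcpc_activity` specification.
#' @export
activity_spec <- function(name, gravity = c(0, 0, 1), harmonics = list(),
                          noise_sd = 0.02) {
  stopifnot(length(gravity) == 3L, noise_sd >= 0)
  for (h in harmonics) {
    stopifnot(h$freq > 0, h$freq < 25, length(h$amp) == 3L)
    if (is.null(h$phase)) h$phase <- 0
  }
  structure(list(name = name, gravity = gravity, harmonics = harmonics,
                 noise_sd = noise_sd), class = "vqcpc_activity")
}

#' Configuration of the synthetic accelerometer dataset
#'
#' @param activities List of [activity_spec()] regimes (>= 2 for
#'   classification tests).
#' @param n_subjects Number of subjects.
#' @param bout_s Seconds per activity bout; each subject's recording
#'   concatenates one bout per activity per cycle, so class priors are
#'   balanced within every subject.
#' @param subject_gain_sd Log-scale SD of the per-subject multiplicative
#'   amplitude gain (LogNormal(0, sd)).
#' @param seed Integer seed; generation is fully deterministic given
#'   (seed, subject).
#' @param rate_hz Sampling rate (default 50).
#' @param n_cycles Number of passes through the activity list per subject.
#' @return A `vqcpc_synth_config`.
#' @export
synth_config <- function(activities, n_subjects = 6L, bout_s = 40,
                         subject_gain_sd = 0.2, seed = 1L, rate_hz = 50,
                         n_cycles = 1L) {
  stopifnot(length(activities) >= 1L, bout_s > 0, n_subjects >= 1L)
  structure(list(activities = activities, n_subjects = n_subjects,
                 bout_s = bout_s, subject_gain_sd = subject_gain_sd,
                 seed = as.integer(seed), rate_hz = rate_hz,
                 n_cycles = as.integer(n_cycles)),
            class = "vqcpc_synth_config")
}

synth_subject_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_subjects))

#' Generate one subject's labelled synthetic recording
#'
#' Every sample is `gravity + sum of harmonics + N(0, noise_sd^2)` per
#' channel; harmonic amplitudes are scaled by the subject's gain and phases
#' are jittered once per (subject, activity, harmonic). The result is
#' deterministic given `(cfg$seed, subject)`.
#'
#' @param cfg A [synth_config()].
#' @param subject Subject id (one of `sprintf("S%02d", 1:n_subjects)`).
#' @return A [new_recording()] with per-sample labels.
#' @export
generate_recording <- function(cfg, subject) {
  n_bout <- as.integer(round(cfg$bout_s * cfg$rate_hz))
  with_seed(derive_seed(cfg$seed, paste0("subject-", subject)), {
    gain <- exp(stats::rnorm(1L, 0, cfg$subject_gain_sd))
    pieces <- list()
    labels <- character(0)
    for (cyc in seq_len(cfg$n_cycles)) {
      for (act in cfg$activities) {
        tt <- (seq_len(n_bout) - 1) / cfg$rate_hz
        S <- matrix(rep(act$gravity, each = n_bout), ncol = 3L)
        for (h in act$harmonics) {
          jitter <- stats::runif(1L, 0, 2 * pi)
          phase <- (h$phase %||% 0) + jitter
          wave <- sin(2 * pi * h$freq * tt + phase)
          S <- S + gain * outer(wave, h$amp)
        }
        if (act$noise_sd > 0) {
          S <- S + matrix(stats::rnorm(n_bout * 3L, 0, act$noise_sd),
                          ncol = 3L)
        }
        pieces[[length(pieces) + 1L]] <- S
        labels <- c(labels, rep(act$name, n_bout))
      }
    }
    new_recording(subject, do.call(rbind, pieces), cfg$rate_hz,
                  labels = labels)
  })
}

#' Generate the full synthetic dataset (one recording per subject)
#'
#' @param cfg A [synth_config()].
#' @return A list of recordings, one per subject; every activity appears in
#'   every subject's recording.
#' @export
generate_dataset <- function(cfg) {
  lapply(synth_subject_ids(cfg), function(s) generate_recording(cfg, s))
}

#' The packaged three-class synthetic benchmark
#'
#' A fixed configuration used throughout the test suite: a near-static
#' "still" class (gravity only, low noise), a "walk_like" class with a 2 Hz
#' gait harmonic, and a "run_like" class with a stronger, noisier 3.5 Hz
#' harmonic. The low-motion class concentrates on few learned symbols while
#' the dynamic classes spread across many, mirroring what per-activity
#' symbol histograms show on real wrist data.
#'
#' @param seed Integer seed.
#' @return A [synth_config()] with 6 subjects and 40 s bouts per activity.
#' @export
default_benchmark <- function(seed = 1L) {
  still <- activity_spec("still", gravity = c(0, 0, 1), harmonics = list(),
                         noise_sd = 0.02)
  walk <- activity_spec("walk_like", gravity = c(0, 0, 1),
                        harmonics = list(
                          list(freq = 2, amp = c(0.40, 0.25, 0.30), phase = 0),
                          list(freq = 4, amp = c(0.10, 0.08, 0.06), phase = 1)),
                        noise_sd = 0.05)
  run <- activity_spec("run_like", gravity = c(0, 0, 1),
                       harmonics = list(
                         list(freq = 3.5, amp = c(0.90, 0.60, 1.00), phase = 0),
                         list(freq = 7, amp = c(0.25, 0.15, 0.20), phase = 2)),
                       noise_sd = 0.10)
  synth_config(list(still, walk, run), n_subjects = 6L, bout_s = 40,
               subject_gain_sd = 0.2, seed = seed)
}
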