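make_rec_df <- function(n = 6L, subject = "A", rate = 50) {
  data.frame(subject = subject, timestamp = (seq_len(n) - 1) / rate,
             x = seq_len(n), y = seq_len(n) + 10, z = seq_len(n) + 20,
             label = rep(c("walk", "run"), length.out = n))
}

test_that("CSV recordings parse per subject with ordered channels", {
  df <- make_rec_df(3)
  recs <- read_recording(write_temp_csv(df))
  expect_length(recs, 1L)
  expect_equal(nrow(recs[[1]]$samples), 3L)
  expect_equal(recs[[1]]$samples[, 1], c(1, 2, 3))
  expect_equal(recs[[1]]$samples[, 3], c(21, 22, 23))
  expect_equal(recs[[1]]$labels, df$label)

  two <- rbind(make_rec_df(3, "A"), make_rec_df(4, "B"))
  recs2 <- read_recording(write_temp_csv(two))
  expect_length(recs2, 2L)
  expect_equal(vapply(recs2, function(r) nrow(r$samples), 0L), c(3L, 4L))
})

test_that("malformed CSV input is rejected", {
  df <- make_rec_df(3)
  df$z <- NULL
  expect_error(read_recording(write_temp_csv(df)), class = "vqcpc_format_error")
  df2 <- make_rec_df(3)
  df2$timestamp <- c(0, 0.04, 0.02)
  expect_error(read_recording(write_temp_csv(df2)), class = "vqcpc_data_error")
})

test_that("recordings round-trip through the CSV writer", {
  rec <- new_recording("S1", matrix(stats::rnorm(30), ncol = 3), 50,
                       labels = rep("a", 10))
  path <- tempfile(fileext = ".csv")
  write_recordings(rec, path)
  back <- read_recording(path, rate_hz = 50)[[1]]
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$labels, rec$labels)
})

test_that("sub-sampling decimates by integer factors only", {
  rec <- new_recording("S1", matrix(seq_len(600), ncol = 3), 100,
                       labels = rep(c("a", "b"), each = 100))
  out <- resample_recording(rec, 50)
  expect_equal(out$rate_hz, 50)
  expect_equal(nrow(out$samples), 100L)
  expect_equal(out$samples[, 1], rec$samples[seq(1, 200, by = 2), 1])
  expect_equal(out$labels, rec$labels[seq(1, 200, by = 2)])

  expect_identical(resample_recording(out, 50), out)
  rec60 <- new_recording("S1", matrix(stats::rnorm(180), ncol = 3), 60)
  expect_error(resample_recording(rec60, 50),
               class = "vqcpc_unsupported_rate")
})

test_that("windowing follows exact stride arithmetic", {
  rec <- new_recording("S1", matrix(stats::rnorm(1200), ncol = 3), 50,
                       labels = rep("a", 400))
  w0 <- make_windows(rec, window_s = 2, overlap_frac = 0)
  expect_length(w0, 4L)
  expect_equal(vapply(w0, `[[`, 0, "start_index"), c(0, 100, 200, 300))
  w5 <- make_windows(rec, window_s = 2, overlap_frac = 0.5)
  expect_length(w5, 7L)
  starts <- vapply(w5, `[[`, 0, "start_index")
  expect_equal(starts, seq(0, 300, by = 50))
  expect_equal(unique(diff(starts)), 50)
  # all windows lie fully inside the recording
  expect_true(all(starts + 100 <= 400))
  expect_equal(w5[[3]]$values, rec$samples[101:200, ])

  short <- new_recording("S1", matrix(stats::rnorm(297), ncol = 3), 50)
  expect_equal(make_windows(short, 2, 0), list())
})

test_that("window labels are majority votes with first-seen tie-break", {
  rec <- new_recording("S1", matrix(0, 100, 3), 50,
                       labels = c(rep("walk", 30), rep("run", 70)))
  expect_equal(make_windows(rec, 2, 0)[[1]]$label, "run")
  tie <- new_recording("S1", matrix(0, 100, 3), 50,
                       labels = rep(c("b", "a"), each = 50))
  expect_equal(make_windows(tie, 2, 0)[[1]]$label, "b")
})

test_that("normalization matches closed-form statistics and round-trips", {
  vals <- matrix(c(rep(c(1, 3), 50), rep(c(-2, 2), 50), rep(5, 100)),
                 ncol = 3)
  rec <- new_recording("S1", rbind(vals, vals), 50)
  wins <- make_windows(rec, 2, 0)
  # constant third channel is degenerate
  expect_error(fit_normalization(wins), class = "vqcpc_degenerate_data")

  vals[, 3] <- rep(c(4, 6), 50)
  rec <- new_recording("S1", rbind(vals, vals), 50)
  wins <- make_windows(rec, 2, 0)
  st <- fit_normalization(wins)
  expect_equal(st$mean, c(2, 0, 5))
  expect_equal(st$std, apply(rbind(vals, vals), 2, stats::sd))

  normed <- apply_normalization(wins, st)
  st2 <- fit_normalization(normed)
  expect_equal(st2$mean, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(st2$std, c(1, 1, 1), tolerance = 1e-12)

  back <- invert_normalization(normed, st)
  expect_equal(back[[1]]$values, wins[[1]]$values, tolerance = 1e-10)
})

test_that("participant folds partition subjects without leakage", {
  subjects <- sprintf("P%02d", 1:10)
  folds <- make_participant_folds(subjects, seed = 3L)
  expect_length(folds, 5L)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2L))
  expect_setequal(unlist(tests), subjects)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_length(intersect(f$train, f$val), 0L)
  }
  # test sets pairwise disjoint
  expect_equal(anyDuplicated(unlist(tests)), 0L)

  expect_identical(folds, make_participant_folds(subjects, seed = 3L))
  expect_false(identical(folds, make_participant_folds(subjects, seed = 4L)))
  expect_error(make_participant_folds(c("a", "b", "c")),
               class = "vqcpc_config_error")
})
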