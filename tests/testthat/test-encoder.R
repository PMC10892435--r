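test_that("valid-convolution arithmetic yields the designed latent counts", {
  base <- encoder_config()
  expect_equal(output_length(100, base), 49L)
  expect_equal(output_frequency(base, 50, 2), 24.5)
  v11 <- encoder_variant(base, 11.5)
  expect_equal(v11$kernels, c(4L, 4L, 1L, 1L))
  expect_equal(v11$strides, c(2L, 2L, 1L, 1L))
  expect_equal(output_length(100, v11), 23L)
  expect_equal(output_frequency(v11, 50, 2), 11.5)
  v50 <- encoder_variant(base, 50)
  expect_equal(output_length(100, v50), 97L)
  ident <- encoder_config(channels = c(8L), kernels = 1L, strides = 1L)
  expect_equal(output_frequency(ident, 50, 2), 50)
  expect_identical(encoder_variant(base, 24.5), base)
  expect_error(encoder_variant(base, 30), class = "vqcpc_config_error")
  expect_error(output_length(3, base), class = "vqcpc_input_too_short")
})

test_that("receptive fields follow the kernel/stride composition", {
  expect_equal(receptive_field(encoder_config()), 4L)
  multi <- encoder_config(channels = c(8L, 8L, 8L), kernels = c(24L, 16L, 8L),
                          strides = c(1L, 1L, 1L))
  expect_equal(receptive_field(multi), 46L)
  one <- encoder_config(channels = 4L, kernels = 1L, strides = 1L)
  expect_equal(receptive_field(one), 1L)
})

test_that("encoding produces the analytic number of latent vectors", {
  cfg <- encoder_config()
  enc <- init_encoder(cfg, seed = 2L)
  X <- random_batch(2L, 100L, seed = 3L)
  Z <- encode(enc, cfg, X)
  expect_equal(dim(Z), c(2L, 49L, 256L))
  Z1 <- encode(enc, cfg, X[, 1:4, , drop = FALSE])
  expect_equal(dim(Z1)[2], 1L)
  # eval mode is a pure function
  expect_identical(Z, encode(enc, cfg, X))
  # zero input with zero biases maps to zero
  expect_true(all(encode(enc, cfg, array(0, c(1, 100, 3))) == 0))
})

test_that("output_length agrees with the realized encode length for random configs", {
  with_seed(11, {
    for (i in 1:8) {
      nb <- sample(2:3, 1)
      cfg <- encoder_config(channels = sample(3:6, nb, TRUE),
                            kernels = sample(1:4, nb, TRUE),
                            strides = sample(1:3, nb, TRUE))
      Tt <- sample(30:60, 1)
      enc <- init_encoder(cfg, seed = i)
      expect_equal(dim(encode(enc, cfg, random_batch(1L, Tt, i)))[2],
                   output_length(Tt, cfg))
    }
  })
})

test_that("dropout perturbs training-mode encoding but not eval mode", {
  cfg <- encoder_config(channels = c(4L, 6L), kernels = c(3L, 2L),
                        strides = c(2L, 1L), dropout_p = 0.5)
  enc <- init_encoder(cfg, seed = 4L)
  X <- random_batch(1L, 20L, seed = 5L)
  set.seed(1)
  a <- encode(enc, cfg, X, train = TRUE)
  set.seed(2)
  b <- encode(enc, cfg, X, train = TRUE)
  expect_false(identical(a, b))
  expect_identical(encode(enc, cfg, X), encode(enc, cfg, X))
})

test_that("perturbing an input sample moves exactly the analytic receptive window", {
  # positive weights and inputs keep every ReLU in its linear region, so
  # finite differences measure the pure convolutional geometry
  cfg <- encoder_config(channels = c(3L, 4L), kernels = c(4L, 1L),
                        strides = c(2L, 1L), dropout_p = 0)
  enc <- init_encoder(cfg, seed = 6L)
  enc <- tree_map(function(p) abs(p) + 0.05, enc)
  X <- array(1, c(1, 12, 3))
  base <- encode(enc, cfg, X)
  rf <- receptive_field(cfg)
  expect_equal(rf, 4L)
  for (s in 1:12) {
    X2 <- X
    X2[1, s, 1] <- 2
    delta <- abs(encode(enc, cfg, X2) - base)
    changed <- which(apply(delta, 2, max) > 1e-12)
    # output step t covers input samples (t-1)*2 + 1 .. (t-1)*2 + rf
    analytic <- which(vapply(seq_len(dim(base)[2]), function(t) {
      s >= (t - 1L) * 2L + 1L && s <= (t - 1L) * 2L + rf
    }, logical(1)))
    expect_equal(changed, analytic)
  }
})
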