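test_that("the aggregator preserves length and strict causality", {
  cfg <- aggregator_config(n_blocks = 2L, channels = 6L, dropout_p = 0)
  agg <- init_aggregator(cfg, seed = 3L)
  Z <- with_seed(4, array(stats::rnorm(2 * 49 * 6), c(2, 49, 6)))
  C <- aggregate_context(agg, cfg, Z)
  expect_equal(dim(C), dim(Z))
  # perturbing step t leaves every earlier context vector exactly unchanged
  for (t in c(1L, 20L, 49L)) {
    Z2 <- Z
    Z2[1, t, ] <- Z2[1, t, ] + 1
    C2 <- aggregate_context(agg, cfg, Z2)
    if (t > 1L) {
      expect_identical(C2[, seq_len(t - 1L), ], C[, seq_len(t - 1L), ])
    }
    expect_false(identical(C2[, t, ], C[, t, ]))
    expect_identical(C2[2, , ], C[2, , ])  # other batch items untouched
  }
})

test_that("zero-weight aggregator blocks reduce to the identity via residuals", {
  cfg <- aggregator_config(n_blocks = 2L, channels = 5L, dropout_p = 0)
  agg <- init_aggregator(cfg, seed = 5L)
  for (i in seq_along(agg)) agg[[i]]$W[] <- 0
  Z <- with_seed(6, array(stats::rnorm(1 * 10 * 5), c(1, 10, 5)))
  expect_equal(aggregate_context(agg, cfg, Z), Z, tolerance = 1e-12)
})

test_that("the contrastive loss hits its closed-form limits", {
  d <- 4L
  C <- with_seed(7, array(stats::rnorm(2 * 8 * d), c(2, 8, d)))
  Zhat <- with_seed(8, array(stats::rnorm(2 * 8 * d), c(2, 8, d)))
  zero_heads <- lapply(1:3, function(k) matrix(0, d, d))
  # all candidate scores equal (zero) -> each term is ln(N+1)
  res <- cpc_loss(C, Zhat, zero_heads, n_negatives = 10L, seed = 1L)
  expect_equal(res$per_k, rep(log(11), 3), tolerance = 1e-12)
  expect_equal(res$total, 3 * log(11), tolerance = 1e-12)
  # a dominant positive score drives the loss toward zero
  Zid <- array(0, c(1, 8, d))
  for (t in 1:8) Zid[1, t, ] <- 1000 * c(sin(t), cos(t), sin(2 * t), cos(2 * t))
  # positive is the future step; align contexts so W_k c_t = z_{t+1}
  Cshift <- Zid
  Cshift[1, 1:7, ] <- Zid[1, 2:8, ]
  sep <- cpc_loss(Cshift, Zid, list(diag(d)), n_negatives = 2L, seed = 2L)
  expect_lt(sep$per_k[1], 1e-6)
})

test_that("a tiny fixed instance matches a hand-rolled softmax cross-entropy oracle", {
  d <- 2L
  Tt <- 4L
  C <- array(0, c(1, Tt, d))
  Zhat <- array(0, c(1, Tt, d))
  C[1, , ] <- matrix(c(0.5, -1, 2, 0.1, -0.3, 1, 0, 0.7), Tt, d, byrow = TRUE)
  Zhat[1, , ] <- matrix(c(1, 0, 0, 1, -1, 1, 0.5, 0.5), Tt, d, byrow = TRUE)
  W <- matrix(c(1, 0.2, -0.1, 0.5), d, d)
  N <- 2L
  res <- cpc_loss(C, Zhat, list(W), n_negatives = N, seed = 42L)

  # independent oracle: replay the seeded negative draws, then score with
  # explicit loops and the log-sum-exp definition
  pool <- matrix(Zhat[1, , ], Tt, d)
  anchors <- 1:3
  pos <- anchors + 1L
  neg <- with_seed(42, {
    r <- sample.int(Tt - 1L, length(anchors) * N, replace = TRUE)
    m <- matrix(r, length(anchors), N)
    m + (m >= pos)
  })
  losses <- vapply(seq_along(anchors), function(i) {
    pred <- as.vector(C[1, anchors[i], ] %*% W)
    scores <- c(sum(pred * pool[pos[i], ]),
                vapply(seq_len(N), function(j) sum(pred * pool[neg[i, j], ]),
                       numeric(1)))
    -log(exp(scores[1]) / sum(exp(scores)))
  }, numeric(1))
  expect_equal(res$per_k[1], mean(losses), tolerance = 1e-12)
})

test_that("the loss breakdown is consistent bookkeeping and reproducible", {
  model <- tiny_model(seed = 11L, dropout = 0.2)
  X <- random_batch(2L, 20L, seed = 12L)
  b1 <- total_loss(model, X, train = TRUE, seed = 13L)
  b2 <- total_loss(model, X, train = TRUE, seed = 13L)
  expect_identical(b1, b2)
  expect_equal(b1$total, b1$cpc + b1$codebook + b1$commitment)
  expect_equal(b1$cpc, sum(b1$per_k))
  expect_true(all(c(b1$cpc, b1$codebook, b1$commitment) >= 0))

  model0 <- tiny_model(seed = 11L)
  model0$cfg$gamma <- 0
  b0 <- total_loss(model0, X, seed = 13L)
  expect_equal(b0$commitment, 0)
  expect_equal(b0$total, b0$cpc + b0$codebook)
})

test_that("aggregator and head gradients agree with finite differences", {
  model <- tiny_model(seed = 21L)
  X <- random_batch(2L, 20L, seed = 22L)
  lossf <- function(m) total_loss(m, X, seed = 23L)$total
  fb <- with_seed(23, model_forward_backward(model, X, train = FALSE))
  eps <- 1e-6
  with_seed(24, {
    for (probe in list(c("agg", "block1", "W"), c("agg", "block2", "ln_g"),
                       c("heads", "1", ""))) {
      if (probe[1] == "heads") {
        p <- model$params$heads[[1]]
        g <- fb$grads$heads[[1]]
      } else {
        p <- model$params[[probe[1]]][[probe[2]]][[probe[3]]]
        g <- fb$grads[[probe[1]]][[probe[2]]][[probe[3]]]
      }
      for (i in sample(length(p), 3)) {
        m2 <- model
        m3 <- model
        if (probe[1] == "heads") {
          m2$params$heads[[1]][i] <- p[i] + eps
          m3$params$heads[[1]][i] <- p[i] - eps
        } else {
          m2$params[[probe[1]]][[probe[2]]][[probe[3]]][i] <- p[i] + eps
          m3$params[[probe[1]]][[probe[2]]][[probe[3]]][i] <- p[i] - eps
        }
        num <- (lossf(m2) - lossf(m3)) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("random-initialization contrastive loss sits at chance level", {
  # ln(N+1) within 0.1 when scores carry no information yet
  d <- 8L
  heads <- init_heads(3L, d, seed = 31L)
  heads <- lapply(heads, function(W) 0.05 * W)
  vals <- with_seed(32, {
    vapply(1:100, function(i) {
      C <- array(stats::rnorm(2 * 12 * d, sd = 0.5), c(2, 12, d))
      Zhat <- array(stats::rnorm(2 * 12 * d, sd = 0.5), c(2, 12, d))
      mean(cpc_forward_backward(C, Zhat, heads, 10L,
                                want_grads = FALSE)$per_k)
    }, numeric(1))
  })
  expect_lt(abs(mean(vals) - log(11)), 0.1)
})

test_that("horizons not shorter than the sequence are rejected", {
  d <- 4L
  C <- array(0, c(1, 3, d))
  heads <- init_heads(3L, d, seed = 1L)
  expect_error(cpc_loss(C, C, heads, 2L, seed = 1L),
               class = "vqcpc_config_error")
})
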