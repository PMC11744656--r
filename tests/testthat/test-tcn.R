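test_that("temporal block preserves length and passes the identity-kernel check", {
  # length preservation across configurations
  for (k in c(1, 2, 3, 5)) for (d in c(1, 2, 4)) {
    p <- with_seed_local(1, temporal_block_params(2, 3, k))
    x <- matrix(runif(2 * 16), 2, 16)
    expect_equal(dim(temporal_block_forward(x, p, dilation = d)), c(3, 16))
  }

  # identity kernels on the current-time tap, zero biases, same channels:
  # main branch reproduces the input, the residual adds it again, so the
  # block computes ReLU(2x) = 2x for non-negative input.
  p <- temporal_block_params(1, 1, 3)
  p$conv1$W[] <- c(0, 0, 1); p$conv1$b[] <- 0
  p$conv2$W[] <- c(0, 0, 1); p$conv2$b[] <- 0
  x <- matrix(c(0.5, 1, 0, 2), 1, 4)
  expect_equal(temporal_block_forward(x, p, dilation = 1), 2 * x)

  # all-zero input with zero weights stays zero
  p0 <- temporal_block_params(1, 2, 3)
  p0$conv1$W[] <- 0; p0$conv1$b[] <- 0
  p0$conv2$W[] <- 0; p0$conv2$b[] <- 0
  p0$down$W[] <- 0; p0$down$b[] <- 0
  expect_equal(temporal_block_forward(matrix(0, 1, 8), p0),
               matrix(0, 2, 8))

  expect_error(temporal_block_forward(matrix(1, 1, 4), p, dilation = 0),
               class = "grnlink_config_error")
})

test_that("the encoder is causal: perturbations never reach earlier positions", {
  cfg <- tcn_config(n_blocks = 3, channel_schedule = c(4, 4, 4),
                    dilation_schedule = c(1, 2, 4), epochs = 0, seed = 2)
  params <- with_seed_local(2, grnlink:::tcn_init_params(cfg))
  L <- 24
  x <- matrix(runif(L), 1, L)
  X <- array(0, c(1, 1, L)); X[1, 1, ] <- x
  Z0 <- grnlink:::tcn_encoder_fwd(X, params, cfg, training = FALSE)$Z
  for (t in c(5, 12, 20)) {
    Xp <- X; Xp[1, 1, t] <- Xp[1, 1, t] + 1
    Zp <- grnlink:::tcn_encoder_fwd(Xp, params, cfg, training = FALSE)$Z
    if (t > 1)
      expect_equal(Zp[, , 1:(t - 1), drop = FALSE], Z0[, , 1:(t - 1), drop = FALSE])
    expect_gt(max(abs(Zp[, , t:L] - Z0[, , t:L])), 0)
  }
})

test_that("mse_loss normalizes by gene count only and matches brute force", {
  expect_equal(mse_loss(diag(3), diag(3)), 0)
  # C = 2, L = 2, unit errors everywhere -> 4/2
  expect_equal(mse_loss(matrix(0, 2, 2), matrix(1, 2, 2)), 2)
  set.seed(9)
  X <- matrix(rnorm(15), 3, 5); Y <- matrix(rnorm(15), 3, 5)
  brute <- 0
  for (j in 1:3) for (k in 1:5) brute <- brute + (X[j, k] - Y[j, k])^2
  expect_equal(mse_loss(X, Y), brute / 3)
  expect_error(mse_loss(X, t(Y)), class = "grnlink_usage_error")
})

test_that("autoencoder training is seeded-reproducible and supports zero epochs", {
  tr <- toy_trajectory(6, 20, seed = 4)
  cfg <- quick_tcn(seed = 9, epochs = 4)
  a <- fit_autoencoder(tr, cfg)
  b <- fit_autoencoder(tr, cfg)
  expect_identical(a$loss, b$loss)
  expect_identical(a$params, b$params)

  init <- fit_autoencoder(tr, quick_tcn(seed = 9, epochs = 0))
  expect_length(init$loss, 0)
  expect_false(init$trained)
  expect_error(encode_trajectory(tr, init), class = "grnlink_usage_error")
})

test_that("encoding gives one latent row per gene; identical profiles map identically", {
  tr <- toy_trajectory(5, 30, seed = 2)
  tr$values[3, ] <- tr$values[1, ]  # duplicate profile
  tr2 <- expression_trajectory(tr$values)
  cfg <- quick_tcn(seed = 1, epochs = 2)
  ae <- fit_autoencoder(tr2, cfg)
  lf <- encode_trajectory(tr2, ae)
  expect_equal(dim(lf$features), c(5L, cfg$latent_dim))
  expect_equal(lf$features[3, ], lf$features[1, ], ignore_attr = TRUE)
  expect_true(all(is.finite(lf$features)))

  rec <- reconstruct(tr2, ae)
  expect_equal(dim(rec), dim(tr2$values))
  expect_gte(mse_loss(tr2$values, rec), 0)
})

test_that("training reduces reconstruction error on a low-rank toy matrix", {
  # rank-1 noiseless pattern; after training the MSE must fall below the
  # baseline of predicting the per-gene mean
  u <- seq(0.5, 2, length.out = 8)
  v <- 1 + sin(seq(0, 2 * pi, length.out = 40))
  tr <- expression_trajectory(outer(u, v))
  # train to convergence: each epoch is one full-batch Adam step, so a
  # larger step size and more epochs are appropriate for this tiny input
  ae <- fit_autoencoder(tr, tcn_config(epochs = 600, learning_rate = 1e-2,
                                       seed = 3))
  rec <- reconstruct(tr, ae)
  baseline <- mse_loss(tr$values, matrix(rowMeans(tr$values), 8, 40))
  expect_lt(mse_loss(tr$values, rec), baseline)
  expect_lt(ae$loss[length(ae$loss)], ae$loss[1])
})
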