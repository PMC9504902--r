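toy_spec <- function() {
  cnn_spec(n_channels = 4, n_samples = 64, conv1_kernels = 3,
           conv2_kernels = 5, conv2_len = 7, pool = 4, dense = 10)
}

test_that("initialization uses N(0, 0.01) weights and unit biases", {
  spec <- cnn_spec(32, 1024)
  p <- init_cnn(spec, seed = 5)
  expect_identical(p$b1, rep(1, 8))
  expect_identical(p$b2, rep(1, 40))
  expect_identical(p$b3, rep(1, 150))
  expect_identical(p$b4, rep(1, 2))
  expect_gt(stats::sd(p$W2), 0.009)   # 40*8*16 draws at sd 0.01
  expect_lt(stats::sd(p$W2), 0.011)
  expect_identical(init_cnn(spec, seed = 5), p)
  expect_false(identical(init_cnn(spec, seed = 6)$W1, p$W1))
})

test_that("the forward pass walks the documented shape chain", {
  spec <- cnn_spec(32, 1024)
  expect_equal(spec$K1, 8)
  expect_equal(spec$K2, 40)
  expect_equal(spec$pooled, 128)
  expect_equal(spec$flat, 5120)
  expect_equal(spec$dense, 150)
  p <- init_cnn(spec, seed = 1)
  set.seed(2)
  batch <- array(stats::rnorm(3 * 32 * 1024), dim = c(3, 32, 1024))
  fw <- cnn_forward(p, batch, spec, keep_cache = TRUE)
  expect_equal(dim(fw$cache$A1), c(8, 1024 * 3))
  expect_equal(dim(fw$cache$A2), c(40, 1024 * 3))
  expect_equal(dim(fw$cache$Fmat), c(5120, 3))
  expect_equal(dim(fw$cache$H), c(150, 3))
  expect_equal(dim(fw$probs), c(3, 2))
  expect_equal(rowSums(fw$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(fw$probs > 0 & fw$probs < 1))
})

test_that("pooled width is floor(T/pool) for any epoch length", {
  for (T in c(64, 100, 1024, 250)) {
    spec <- cnn_spec(4, T, conv1_kernels = 3, conv2_kernels = 5,
                     conv2_len = 7, pool = 8, dense = 6)
    expect_equal(spec$pooled, T %/% 8)
    p <- init_cnn(spec, 1)
    pr <- cnn_forward(p, array(stats::rnorm(2 * 4 * T), dim = c(2, 4, T)),
                      spec)
    expect_equal(dim(pr), c(2, 2))
  }
})

test_that("softmax probabilities are invariant to a shared bias shift", {
  spec <- toy_spec()
  p <- init_cnn(spec, 3)
  set.seed(1)
  batch <- array(stats::rnorm(2 * 4 * 64), dim = c(2, 4, 64))
  p2 <- p
  p2$b4 <- p$b4 + 3.5
  expect_equal(cnn_forward(p, batch, spec), cnn_forward(p2, batch, spec),
               tolerance = 1e-12)
})

test_that("shape mismatches are rejected", {
  spec <- toy_spec()
  p <- init_cnn(spec, 1)
  expect_error(cnn_forward(p, array(0, dim = c(2, 5, 64)), spec),
               "does not match spec")
})

test_that("compiled and reference forward/backward passes agree", {
  spec <- toy_spec()
  p <- init_cnn(spec, 3)
  p <- lapply(p, function(w) {
    w + stats::rnorm(length(w), 0, 0.05) * rep(1, length(w))
  })
  for (nm in c("W1", "W2", "W3", "W4")) dim(p[[nm]]) <-
      dim(init_cnn(spec, 1)[[nm]])
  set.seed(8)
  batch <- array(stats::rnorm(4 * 4 * 64), dim = c(4, 4, 64))
  y <- c(0L, 1L, 1L, 0L)
  ref <- smrdecode:::cnn_loss_grad(p, spec, batch, y)
  X <- smrdecode:::batch_to_mat(batch)
  W2m <- matrix(p$W2, spec$K2, spec$K1 * spec$klen)
  got <- smrdecode:::cnn_pass(X, p$W1, p$b1, W2m, p$b2, p$W3, p$b3, p$W4,
                              p$b4, spec$T, 4L, spec$pool, spec$klen,
                              spec$padl, y, TRUE)
  expect_equal(got$loss, ref$loss, tolerance = 1e-12)
  expect_equal(array(got$dW2, dim = dim(p$W2)), ref$grads$W2,
               tolerance = 1e-12)
  expect_equal(got$dW1, ref$grads$W1, tolerance = 1e-12)
  expect_equal(drop(got$db3), ref$grads$b3, tolerance = 1e-12)
})

test_that("training reduces loss on separable data, deterministically", {
  ds <- tiny_dataset(n_per = 25, erd = 0.9, snr = 4, fs = 512,
                     trial_len = 2, seed = 31)
  cfg <- train_config(alpha0 = 1e-2, batch_size = 8, max_epochs = 12,
                      patience = 12, max_lr_drops = 0, seed = 2)
  fit <- train_cnn(ds, cfg)
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(h$lr %in% (1e-2 / 3^(0:3))))
  fit2 <- train_cnn(ds, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
  pred <- predict(fit, ds, type = "class")
  expect_gt(mean(pred == ds$labels), 0.6)

  ds1 <- ds
  ds1$labels <- rep(0L, length(ds$labels))
  expect_error(train_cnn(ds1, cfg), "both classes")
})

test_that("the learning-rate schedule divides by three and terminates", {
  ds <- noise_epochs(n_trials = 16, n_samples = 64)
  cfg <- train_config(alpha0 = 9e-3, batch_size = 8, max_epochs = 30,
                      patience = 1, max_lr_drops = 3, seed = 4)
  fit <- train_cnn(ds, cfg)
  lrs <- unique(fit$history$lr)
  expect_true(all(abs(lrs / (9e-3 / 3^(seq_along(lrs) - 1)) - 1) < 1e-12))
  expect_lte(length(lrs), 4)   # initial rate plus at most three reductions
})

test_that("channel importance reflects the spatial-layer weights", {
  spec <- toy_spec()
  p <- init_cnn(spec, 1)
  p$W1 <- matrix(0.5, spec$K1, spec$C)
  expect_equal(cnn_channel_importance(p), rep(0.5, 4))
  p$W1[, 3] <- 0
  sc <- cnn_channel_importance(p)
  expect_equal(sc[3], 0)
  expect_true(all(sc >= 0))
})
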