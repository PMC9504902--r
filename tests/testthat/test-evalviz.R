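constant_decoder <- function(value = 0L) {
  decoder_pipeline("custom",
                   fit = function(train, seed) value,
                   predict = function(fit, test) {
                     rep(fit, smrdecode:::n_trials(test))
                   })
}

majority_decoder <- function() {
  decoder_pipeline("custom",
                   fit = function(train, seed) {
                     as.integer(mean(train$labels) > 0.5)
                   },
                   predict = function(fit, test) {
                     rep(fit, smrdecode:::n_trials(test))
                   })
}

test_that("the binomial chance level is an exact tail computation", {
  # n = 20: P(X >= 15) ~ 0.0207 <= 0.05 < P(X >= 14) ~ 0.0577
  expect_equal(binomial_chance_level(20, 2, 0.05), 15 / 20)
  expect_equal(1 - stats::pbinom(14, 20, 0.5), 0.02069473, tolerance = 1e-6)
  expect_equal(1 - stats::pbinom(13, 20, 0.5), 0.05765915, tolerance = 1e-6)

  th <- vapply(c(20, 100, 1000), binomial_chance_level, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_gt(min(th), 0.5)

  expect_equal(binomial_chance_level(10, 2, 1), 0)
})

test_that("stratified folds have balanced sizes and seeded assignment", {
  ds <- noise_epochs(n_trials = 60, n_samples = 32)
  res <- kfold_cv(ds, constant_decoder(), k = 10, seed = 5)
  expect_equal(nrow(res$folds), 10)
  expect_true(all(res$folds$n_test == 6))
  res2 <- kfold_cv(ds, constant_decoder(), k = 10, seed = 5)
  expect_identical(res$folds, res2$folds)
  expect_error(kfold_cv(ds, constant_decoder(), k = 40, seed = 1),
               "exceeds the smaller class")
})

test_that("a constant pipeline scores one half on balanced data", {
  ds <- noise_epochs(n_trials = 40, n_samples = 32)
  res <- kfold_cv(ds, constant_decoder(0L), k = 5, seed = 2)
  expect_equal(res$mean_accuracy, 0.5)
  res1 <- kfold_cv(ds, constant_decoder(1L), k = 5, seed = 2)
  expect_equal(res1$mean_accuracy, 0.5)
})

test_that("fold models never see their test labels", {
  ds <- tiny_dataset(n_per = 8, erd = 0.9, snr = 4, seed = 71)
  spec <- decoder_pipeline("csp-svm", n_pairs = 2, n_features = 10)
  tr <- smrdecode:::subset_epochs(ds, 1:10)
  te <- smrdecode:::subset_epochs(ds, 11:16)
  fit <- fit_decoder(spec, tr, seed = 1)
  pred <- predict(fit, te)
  te_flipped <- te
  te_flipped$labels <- 1L - te$labels
  expect_identical(predict(fit, te_flipped), pred)
})

test_that("decoding results summarize and report cleanly", {
  ds <- noise_epochs(n_trials = 30, n_samples = 32)
  res <- kfold_cv(ds, majority_decoder(), k = 5, seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 5)
  expect_true(all(c("fold", "accuracy") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$k, 5)
  expect_equal(gl$chance_level, binomial_chance_level(30))
  expect_s3_class(autoplot(res), "ggplot")

  file <- withr::local_tempfile(fileext = ".json")
  run_report(res, file)
  back <- jsonlite::read_json(file, simplifyVector = TRUE)
  expect_equal(back$mean_accuracy, res$mean_accuracy)
  expect_length(back$fold_accuracies, 5)
})

test_that("training histories expose tidy and autoplot methods", {
  ds <- tiny_dataset(n_per = 6, erd = 0.9, snr = 4, seed = 72)
  fit <- train_cnn(ds, train_config(alpha0 = 1e-2, batch_size = 8,
                                    max_epochs = 2, patience = 2,
                                    max_lr_drops = 0, seed = 1))
  h <- tidy(fit)
  expect_true(all(c("epoch", "loss", "val_error", "lr") %in% names(h)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$epochs, nrow(h))
})

test_that("topographic interpolation anchors extremes at the channels", {
  m <- generate_montage(32)
  flat <- interpolate_topography(rep(2.2, 32), m)
  expect_lt(diff(range(flat$value, na.rm = TRUE)), 1e-9)

  hot <- rep(0, 32)
  hot[channel_index(m, "C3")] <- 1
  df <- interpolate_topography(hot, m, grid_n = 101)
  top <- df[which.max(df$value), ]
  expect_equal(c(top$x, top$y), unname(m$pos["C3", ]), tolerance = 0.03)

  expect_error(interpolate_topography(rep(1, 5), m), "does not match")
})

test_that("rendered topographies are byte-identical for fixed inputs", {
  m <- generate_montage(16)
  sc <- seq_len(16) / 16
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_topography(sc, m, f1)
  render_topography(sc, m, f2)
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
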