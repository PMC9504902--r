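gauss_features <- function(n = 40, n_noise = 20, delta = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, each = n / 2)
  info <- matrix(stats::rnorm(n * 2), n, 2)
  info[labels == 1, ] <- info[labels == 1, ] + delta
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  X <- cbind(info, noise)
  colnames(X) <- c("info1", "info2", paste0("noise", seq_len(n_noise)))
  list(X = X, labels = labels)
}

test_that("a feature identical across classes has zero power", {
  g <- gauss_features(seed = 2)
  g$X[, "noise1"] <- rep(c(1, 2), length.out = nrow(g$X))  # class-independent
  g$X[, "noise2"] <- 5                                      # constant
  expect_message(rk <- cva_rank(g$X, g$labels), "zero within-class")
  expect_equal(rk$power[rk$feature == "noise2"], 0)
  id <- g$X[, 1] * 0 + g$labels   # perfectly class-locked, zero within
  X2 <- cbind(g$X, locked = id)
  expect_message(rk2 <- cva_rank(X2, g$labels), "zero within-class")
  expect_equal(rk2$power[rk2$feature == "locked"], 0)
})

test_that("well-separated features outrank noise almost always", {
  wins <- 0
  for (s in 1:100) {
    g <- gauss_features(n = 30, n_noise = 10, delta = 3, seed = s)
    rk <- cva_rank(g$X, g$labels)
    top2 <- rk$feature[order(rk$rank)][1:2]
    wins <- wins + as.integer(all(top2 %in% c("info1", "info2")))
  }
  expect_gte(wins, 95)
})

test_that("label permutation collapses the discriminant power", {
  g <- gauss_features(n = 40, n_noise = 10, delta = 3, seed = 5)
  obs <- max(cva_rank(g$X, g$labels)$power)
  set.seed(6)
  perm <- replicate(100, max(cva_rank(g$X, sample(g$labels))$power))
  expect_lt(stats::median(perm), obs)
})

test_that("the full Fisher direction separates the class means", {
  g <- gauss_features(n = 60, n_noise = 5, delta = 2, seed = 7)
  rk <- cva_rank(g$X, g$labels, direction = TRUE)
  w <- attr(rk, "direction")
  expect_length(w, ncol(g$X))
  proj <- g$X %*% w
  expect_gt(mean(proj[g$labels == 1]) - mean(proj[g$labels == 0]), 0)
})

test_that("feature-count selection minimizes validation error", {
  g <- gauss_features(n = 60, n_noise = 30, delta = 3, seed = 9)
  tr <- seq_len(40)
  va <- 41:60
  sel <- select_feature_count(g$X[tr, ], g$labels[tr], g$X[va, ],
                              g$labels[va], grid = c(2, 8, 32))
  expect_true(sel$best %in% c(2, 8, 32))
  expect_equal(nrow(sel$curve), 3)
  expect_equal(sel$curve$val_error[sel$curve$n_features == sel$best],
               min(sel$curve$val_error))

  single <- select_feature_count(g$X[tr, ], g$labels[tr], g$X[va, ],
                                 g$labels[va], grid = 32)
  expect_equal(single$best, 32)
  expect_error(select_feature_count(g$X[tr, ], g$labels[tr], g$X[va, ],
                                    g$labels[va], grid = integer(0)),
               "empty")
  expect_error(select_feature_count(g$X[tr, ], g$labels[tr], g$X[va, ],
                                    g$labels[va], grid = 1000),
               "above the number")
})

test_that("ties in validation error resolve to the smaller count", {
  # two informative features; counts 2 and 10 both classify perfectly
  g <- gauss_features(n = 60, n_noise = 8, delta = 6, seed = 11)
  sel <- select_feature_count(g$X[1:40, ], g$labels[1:40], g$X[41:60, ],
                              g$labels[41:60], grid = c(10, 2))
  expect_equal(sel$best, 2)
})

test_that("planted sparse structure keeps the selected count small", {
  hits <- 0
  for (s in 1:10) {
    g <- gauss_features(n = 60, n_noise = 90, delta = 2.5, seed = 100 + s)
    sel <- select_feature_count(g$X[1:40, ], g$labels[1:40], g$X[41:60, ],
                                g$labels[41:60],
                                grid = c(2, 5, 10, 25, 50, 92))
    hits <- hits + as.integer(sel$best <= 25)
  }
  expect_gte(hits, 8)
})

test_that("channel topographies aggregate power across frequency bins", {
  ds <- tiny_dataset(n_per = 5, seed = 21)
  ft <- multitaper_psd(ds)
  rk <- cva_rank(ft)
  m <- ds$montage

  # synthetic ranking with one hot feature at (C3, 10 Hz)
  rk0 <- rk
  rk0$power <- rep(0, nrow(rk0))
  rk0$power[rk0$feature == "C3_10Hz"] <- 2.5
  topo <- cva_topography(rk0, m)
  expect_equal(unname(topo["C3"]), 2.5 / 22)
  expect_equal(sum(topo != 0), 1)

  rk1 <- rk
  rk1$power <- rep(1.5, nrow(rk1))
  expect_equal(unname(cva_topography(rk1, m)), rep(1.5, 16))
})
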