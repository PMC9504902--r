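test_that("pink noise is deterministic, zero-mean and ~1/f", {
  x1 <- pink_noise(2^14, seed = 9)
  x2 <- pink_noise(2^14, seed = 9)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1)), 5 / sqrt(2^14))   # 5 standard errors of unit RMS
  expect_error(pink_noise(1, seed = 1), "at least 2")

  x <- pink_noise(2^16, seed = 3)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 512), plot = FALSE,
                          taper = 0)
  sel <- sp$freq > 2 & sp$freq < 60
  slope <- stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_gt(slope, -1.5)
  expect_lt(slope, -0.5)
})

test_that("simulated trials have the contracted shape and determinism", {
  p <- sim_params(n_trials_per_class = 2, n_channels = 16, fs = 160,
                  trial_len = 2.5, seed = 1)
  m <- generate_montage(16)
  tr1 <- simulate_trial(0, p, m, seed = 5)
  tr2 <- simulate_trial(0, p, m, seed = 5)
  expect_identical(tr1, tr2)
  expect_equal(dim(tr1), c(16, round(160 * 2.5)))
  expect_true(all(is.finite(tr1)))
})

test_that("planted ERD suppresses contralateral mu power", {
  p <- sim_params(n_trials_per_class = 2, n_channels = 16, fs = 160,
                  trial_len = 2, erd_depth = 0.8, snr = 2, seed = 1)
  m <- generate_montage(16)
  i4 <- channel_index(m, "C4")
  bp <- function(cls, sd) {
    band_power(simulate_trial(cls, p, m, seed = sd)[i4, ], 160, 8, 12)
  }
  left <- vapply(1:40, function(s) bp(0, s), numeric(1))
  right <- vapply(41:80, function(s) bp(1, s), numeric(1))
  # class 0 (left hand) suppresses C4: lower mu power than class 1 trials
  expect_lt(mean(left), mean(right))
  expect_lt(stats::t.test(left, right)$p.value, 0.01)
})

test_that("no ERD means no class difference in band power", {
  p <- sim_params(n_trials_per_class = 2, n_channels = 16, fs = 160,
                  trial_len = 2, erd_depth = 0, snr = 2, seed = 1)
  m <- generate_montage(16)
  idx <- channel_index(m, c("C3", "C4"))
  bp <- function(cls, sd) {
    tr <- simulate_trial(cls, p, m, seed = sd)
    band_power(tr[idx[1], ], 160, 8, 12) + band_power(tr[idx[2], ], 160, 8, 12)
  }
  a <- vapply(1:50, function(s) bp(0, s), numeric(1))
  b <- vapply(101:150, function(s) bp(1, s), numeric(1))
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
  # identical seeds make the two classes identical when nothing is planted
  b_same <- vapply(1:50, function(s) bp(1, s), numeric(1))
  expect_equal(a, b_same, tolerance = 1e-12)
})

test_that("datasets are balanced, shuffled and reproducible", {
  p <- sim_params(n_trials_per_class = 6, n_channels = 16, fs = 160,
                  trial_len = 2, seed = 7)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$labels, d2$labels)
  expect_equal(dim(d1$data), c(12, 16, 320))
  expect_equal(as.vector(table(d1$labels)), c(6, 6))
  # shuffled: not all of one class first
  expect_gt(length(rle(d1$labels)$lengths), 2)
})

test_that("class contrast grows with ERD depth", {
  contrast <- function(erd) {
    ds <- tiny_dataset(n_per = 10, erd = erd, seed = 11)
    i <- channel_index(ds$montage, c("C3", "C4"))
    bp <- function(tr, ch) band_power(ds$data[tr, ch, ], ds$fs, 8, 30)
    d3 <- vapply(seq_len(20), bp, numeric(1), ch = i[1])
    d4 <- vapply(seq_len(20), bp, numeric(1), ch = i[2])
    # lateralization index contrast between classes
    li <- log(d3) - log(d4)
    abs(mean(li[ds$labels == 0]) - mean(li[ds$labels == 1]))
  }
  cs <- vapply(c(0, 0.4, 0.8), contrast, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("the epoch container round-trips bit-exactly", {
  ds <- noise_epochs(n_trials = 4, n_samples = 32)
  dir <- withr::local_tempdir()
  write_epochs(ds, dir)
  back <- read_epochs(dir)
  expect_identical(back$data, ds$data)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$fs, ds$fs)
  expect_identical(back$montage$names, ds$montage$names)
})

test_that("parameter validation rejects inconsistent configurations", {
  expect_error(sim_params(erd_depth = 1.2), "erd_depth")
  expect_error(sim_params(fs = 50), "twice the highest band edge")
  expect_error(sim_params(trial_len = 0), "trial_len")
  m <- generate_montage(16)
  p <- sim_params(n_channels = 16, focus_channels = "T7")
  expect_error(simulate_trial(0, p, m, 1), "not in montage")
})
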