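make_recording <- function(n_ch = 16, n_samp = 2000, fs = 160, seed = 2,
                           events = data.frame(sample = c(100, 600, 1200),
                                               label = c(0, 1, 0))) {
  m <- generate_montage(n_ch)
  set.seed(seed)
  eeg_recording(matrix(stats::rnorm(n_ch * n_samp), n_ch, n_samp), fs,
                events, m)
}

test_that("downsampling scales lengths and preserves spectral peaks", {
  m <- generate_montage(16)
  fs <- 2048
  t <- (0:(4 * fs - 1)) / fs
  x <- array(rep(sin(2 * pi * 10 * t), each = 16), dim = c(1, 16, 4 * fs))
  es <- epoch_set(x, 0L, fs, m)
  down <- downsample(es, 512)
  expect_equal(dim(down$data)[3], 2048)   # 4 s at 512 Hz
  expect_equal(down$fs, 512)
  sp <- stats::spec.pgram(stats::ts(down$data[1, 1, ], frequency = 512),
                          plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 10), 0.5)

  expect_identical(downsample(es, fs)$data, es$data)
  expect_error(downsample(es, 4096), "exceeds")
})

test_that("event indices are rescaled when downsampling a recording", {
  rec <- make_recording(fs = 160, n_samp = 1600)
  down <- downsample(rec, 80)
  expect_equal(ncol(down$data), 800)
  expect_equal(down$events$sample, floor((rec$events$sample - 1) / 2) + 1)
})

test_that("epoch extraction follows the half-open window convention", {
  rec <- make_recording(fs = 160, n_samp = 2000)
  ep <- extract_epochs(rec, preproc_config(epoch_window = c(0, 2)))
  expect_equal(dim(ep$data), c(3, 16, 320))
  expect_equal(ep$labels, c(0L, 1L, 0L))
  # epoch 1 starts exactly at the cue sample
  expect_equal(ep$data[1, 1, ], rec$data[1, 100:419])

  half <- extract_epochs(rec, preproc_config(epoch_window = c(0, 0.5)))
  expect_equal(dim(half$data)[3], 80)
})

test_that("out-of-bounds epochs are dropped with a warning", {
  rec <- make_recording(n_samp = 700,
                        events = data.frame(sample = c(100, 300, 650),
                                            label = c(0, 1, 0)))
  expect_warning(
    ep <- extract_epochs(rec, preproc_config(epoch_window = c(0, 2))),
    "out of bounds"
  )
  expect_equal(dim(ep$data)[1], 2)
  rec2 <- make_recording(n_samp = 150,
                         events = data.frame(sample = 100, label = 0))
  expect_error(
    suppressWarnings(extract_epochs(rec2,
                                    preproc_config(epoch_window = c(0, 2)))),
    "all epochs"
  )
})

test_that("the small Laplacian subtracts the orthogonal-neighbour mean", {
  m <- generate_montage(16)
  # spatially constant field is annihilated
  const <- epoch_set(array(3.7, dim = c(1, 16, 8)), 0L, 160, m)
  expect_equal(max(abs(small_laplacian(const)$data)), 0)

  # a channel at 5 with all four neighbours at 1 maps to 4
  x <- array(1, dim = c(1, 16, 4))
  i <- channel_index(m, "C1")      # interior channel, 4 neighbours
  x[1, i, ] <- 5
  lap <- small_laplacian(epoch_set(x, 0L, 160, m))
  expect_equal(unname(lap$data[1, i, 1]), 4)

  # adding a constant to every channel leaves the output unchanged
  ds <- noise_epochs(n_trials = 2, n_samples = 16)
  shifted <- ds
  shifted$data <- ds$data + 11.3
  expect_equal(small_laplacian(shifted)$data, small_laplacian(ds)$data)

  # not idempotent
  l1 <- small_laplacian(ds)
  l2 <- small_laplacian(l1)
  expect_gt(max(abs(l2$data - l1$data)), 1e-6)
})

test_that("standardization fits, applies and guards degenerate channels", {
  ds <- noise_epochs(n_trials = 10, n_samples = 50)
  ds$data <- ds$data * 4 + 2
  std <- standardize(ds)
  stats <- attr(std, "scaling")
  flat <- matrix(aperm(std$data, c(2, 1, 3)), nrow = 16)
  expect_equal(unname(rowMeans(flat)), rep(0, 16), tolerance = 1e-10)
  expect_equal(unname(apply(flat, 1, stats::sd)), rep(1, 16),
               tolerance = 1e-2)

  # stats from split A applied to split B: B is not exactly zero-mean
  other <- noise_epochs(n_trials = 10, n_samples = 50, seed = 99)
  stdB <- standardize(other, stats = stats)
  flatB <- matrix(aperm(stdB$data, c(2, 1, 3)), nrow = 16)
  expect_gt(max(abs(rowMeans(flatB))), 1e-3)

  flatds <- ds
  flatds$data[, 3, ] <- 0
  expect_warning(sf <- standardize(flatds), "zero variance")
  expect_equal(unname(sf$data[, 3, ]), ds$data[, 3, ] * 0)
})

test_that("epoching and downsampling commute up to resampler edge effects", {
  rec <- make_recording(fs = 160, n_samp = 3200,
                        events = data.frame(sample = c(161, 1601),
                                            label = c(0, 1)))
  a <- downsample(extract_epochs(rec, preproc_config(epoch_window = c(0, 2))),
                  80)
  b <- extract_epochs(downsample(rec, 80),
                      preproc_config(epoch_window = c(0, 2)))
  expect_equal(dim(a$data), dim(b$data))
  # compare away from the epoch edges (the resampler filter warms up)
  core <- 20:140
  expect_lt(stats::median(abs(a$data[, , core] - b$data[, , core])), 0.05)
})
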