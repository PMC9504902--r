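# Shared fixtures: all data is generated in code at test time.

# small hand-imagery dataset (16 channels keeps everything fast)
tiny_dataset <- function(n_per = 15, erd = 0.8, snr = 2, fs = 160,
                         trial_len = 2, n_channels = 16, seed = 42,
                         focus = c("C3", "C4")) {
  simulate_dataset(sim_params(
    n_trials_per_class = n_per, n_channels = n_channels, fs = fs,
    trial_len = trial_len, erd_depth = erd, snr = snr,
    focus_channels = focus, seed = seed
  ))
}

# unstructured epochs for plumbing tests (no simulation cost)
noise_epochs <- function(n_trials = 20, n_channels = 16, n_samples = 64,
                         fs = 160, seed = 1) {
  m <- generate_montage(n_channels)
  set.seed(seed)
  epoch_set(array(stats::rnorm(n_trials * n_channels * n_samples),
                  dim = c(n_trials, n_channels, n_samples)),
            rep_len(0:1, n_trials), fs, m)
}

# central finite-difference gradient of a scalar loss over a parameter list
numeric_gradient <- function(loss_fn, params, nm, eps = 1e-6) {
  g <- params[[nm]] * 0
  for (i in seq_along(params[[nm]])) {
    pp <- params
    pp[[nm]][i] <- pp[[nm]][i] + eps
    up <- loss_fn(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    dn <- loss_fn(pp)
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) max(abs(a - b)) / max(abs(b) + 1e-8)

# independent scalar oracles for the optimizer recursions
adam_scalar_oracle <- function(g_seq, alpha, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, w0 = 0) {
  w <- w0; V <- 0; S <- 0
  out <- numeric(length(g_seq))
  for (t in seq_along(g_seq)) {
    g <- g_seq[t]
    V <- beta1 * V + (1 - beta1) * g
    S <- beta2 * S + (1 - beta2) * g^2
    vh <- V / (1 - beta1^t)
    sh <- S / (1 - beta2^t)
    w <- w - alpha * vh / (sqrt(sh) + eps)
    out[t] <- w
  }
  out
}

rmsprop_scalar_oracle <- function(g_seq, alpha, beta = 0.9, eps = 1e-8,
                                  w0 = 0) {
  w <- w0; S <- 0
  out <- numeric(length(g_seq))
  for (t in seq_along(g_seq)) {
    g <- g_seq[t]
    S <- beta * S + (1 - beta) * g^2
    w <- w - alpha * g / sqrt(S + eps)
    out[t] <- w
  }
  out
}

# focus-channel neighbourhood (labels of the foci plus their orthogonal
# neighbours)
focus_neighborhood <- function(montage, focus) {
  idx <- channel_index(montage, focus)
  unique(c(focus, montage$names[unlist(montage$neighbors[idx])]))
}

# Welch-style band power of one channel of one trial
band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
}
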