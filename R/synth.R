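#' Simulation parameters for synthetic sensorimotor-rhythm EEG
#'
#' The generator plants event-related desynchronization (ERD) of mu
#' (8--12 Hz) and beta (14--30 Hz) oscillations over the sensorimotor strip
#' on a 1/f noise background. For a hand-imagery configuration (two focus
#' channels, e.g. C3/C4), the class label codes the imagined hand and the
#' *contralateral* focus channel has its oscillation amplitude attenuated by
#' a factor `1 - erd_depth`. For a lower-limb configuration (single midline
#' focus, Cz), the class is coded by which band desynchronizes: class 0
#' attenuates mu, class 1 attenuates beta.
#'
#' @param n_trials_per_class Trials per class.
#' @param n_channels Montage layout size (16, 32 or 64).
#' @param fs Sampling rate, Hz. Must exceed twice the highest band edge.
#' @param trial_len Trial length, seconds.
#' @param erd_depth ERD attenuation fraction in `[0, 1]`; 0 plants no effect.
#' @param snr Ratio of rhythm RMS to noise RMS at the focus channels.
#' @param focus_channels Labels of the oscillation foci; a mirror pair for
#'   hand imagery or a single midline channel for lower-limb imagery.
#' @param bands List of `(low, high)` Hz pairs; default mu and beta.
#' @param seed Integer seed; all outputs are pure functions of
#'   `(params, seed)`.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_trials_per_class = 150, n_channels = 32, fs = 512,
                       trial_len = 4, erd_depth = 0.8, snr = 2,
                       focus_channels = c("C3", "C4"),
                       bands = list(mu = c(8, 12), beta = c(14, 30)),
                       seed = 1L) {
  stopifnot_scalar_count(n_trials_per_class, "n_trials_per_class")
  if (erd_depth < 0 || erd_depth > 1) {
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  }
  if (trial_len <= 0) stop("trial_len must be positive", call. = FALSE)
  fmax <- max(vapply(bands, max, numeric(1)))
  if (fs <= 2 * fmax) {
    stop("fs must exceed twice the highest band edge (", 2 * fmax, " Hz)",
         call. = FALSE)
  }
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels), fs = fs, trial_len = trial_len,
         erd_depth = erd_depth, snr = snr, focus_channels = focus_channels,
         bands = bands, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' 1/f (pink) background noise
#'
#' Spectral-synthesis pink noise: Gaussian white noise is shaped in the
#' frequency domain by `1/sqrt(f)` so its power spectrum decays as `1/f`,
#' then normalized to zero mean and unit RMS.
#'
#' @param n_samples Number of samples (at least 2).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Numeric vector of length `n_samples`, zero mean, unit RMS.
#' @export
pink_noise <- function(n_samples, seed) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be at least 2", call. = FALSE)
  }
  n <- as.integer(n_samples)
  with_seed(seed, {
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    k <- seq_len(n) - 1L
    f_eff <- pmin(k, n - k)          # two-sided frequency index
    scale <- ifelse(f_eff == 0, 0, 1 / sqrt(f_eff))
    x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
    x <- x - mean(x)
    x / rms(x)
  })
}

# Band oscillation: band-centre sinusoid with per-trial random phase and a
# slow raised-cosine amplitude envelope, rescaled to an exact target RMS.
band_oscillation <- function(n, fs, band, target_rms, mod_depth = 0.5,
                             mod_freq = 1) {
  t <- (seq_len(n) - 1) / fs
  fc <- mean(band)
  phase <- stats::runif(1, 0, 2 * pi)
  mod_phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + mod_depth * cos(2 * pi * mod_freq * t + mod_phase)
  s <- env * sin(2 * pi * fc * t + phase)
  s / rms(s) * target_rms
}

# Rhythm RMS at a focus channel for snr = 1 noise; microvolt scale.
RHYTHM_RMS_UV <- 5
SPREAD_SPACE_CONSTANT <- 0.35  # head radii

#' Simulate one motor-imagery trial
#'
#' Each channel is 1/f noise plus band-limited oscillations generated at the
#' focus channels and spread to neighbouring channels with an exponential
#' distance decay (space constant 0.35 head radii). The planted ERD follows
#' the class label as described in [sim_params()].
#'
#' @param class_label 0 or 1.
#' @param params A [sim_params()] object.
#' @param montage A [generate_montage()] object containing the focus channels.
#' @param seed Integer seed for this trial.
#' @return Numeric matrix, `channels x samples` (microvolts).
#' @export
simulate_trial <- function(class_label, params, montage, seed) {
  focus_idx <- channel_index(montage, params$focus_channels)
  n <- round(params$fs * params$trial_len)
  n_ch <- length(montage$names)
  n_bands <- length(params$bands)
  n_foci <- length(focus_idx)
  # oscillation RMS per band so the summed rhythm RMS is RHYTHM_RMS_UV
  # (independent bands add in power)
  band_rms <- RHYTHM_RMS_UV / sqrt(n_bands)
  noise_rms <- RHYTHM_RMS_UV / params$snr

  # attenuation factor per (focus, band)
  atten <- matrix(1, n_foci, n_bands)
  if (n_foci >= 2) {
    # hand imagery: class 0 = left hand suppresses the right-hemisphere focus
    # (positive x), class 1 the left-hemisphere focus; all bands attenuated
    xpos <- montage$pos[focus_idx, 1]
    target <- if (class_label == 0) which.max(xpos) else which.min(xpos)
    atten[target, ] <- 1 - params$erd_depth
  } else {
    # lower-limb imagery at a midline focus: class selects the band
    band_target <- if (class_label == 0) 1L else min(2L, n_bands)
    atten[1, band_target] <- 1 - params$erd_depth
  }

  with_seed(seed, {
    out <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      out[ch, ] <- noise_rms * local_pink(n)
    }
    for (fi in seq_len(n_foci)) {
      d <- sqrt(colSums((t(montage$pos) - montage$pos[focus_idx[fi], ])^2))
      gain <- exp(-d / SPREAD_SPACE_CONSTANT)
      for (bi in seq_len(n_bands)) {
        s <- band_oscillation(n, params$fs, params$bands[[bi]],
                              band_rms * atten[fi, bi])
        out <- out + outer(gain, s)
      }
    }
    rownames(out) <- montage$names
    out
  })
}

# pink noise drawing from the *current* RNG stream (used inside with_seed)
local_pink <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq_len(n) - 1L
  f_eff <- pmin(k, n - k)
  scale <- ifelse(f_eff == 0, 0, 1 / sqrt(f_eff))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / rms(x)
}

#' Simulate a labelled motor-imagery dataset
#'
#' Generates `2 * n_trials_per_class` trials with balanced classes, shuffled
#' deterministically by `params$seed`, on the montage implied by
#' `params$n_channels`.
#'
#' @param params A [sim_params()] object.
#' @param montage Optional pre-built montage; defaults to
#'   `generate_montage(params$n_channels)`.
#' @return An [epoch_set()].
#' @export
simulate_dataset <- function(params, montage = NULL) {
  montage <- montage %||% generate_montage(params$n_channels)
  n_per <- params$n_trials_per_class
  n_tot <- 2L * n_per
  labels <- rep(0:1, each = n_per)
  ord <- with_seed(params$seed, sample.int(n_tot))
  labels <- labels[ord]
  n_samp <- round(params$fs * params$trial_len)
  data <- array(0, dim = c(n_tot, length(montage$names), n_samp))
  for (i in seq_len(n_tot)) {
    data[i, , ] <- simulate_trial(labels[i], params, montage,
                                  seed = child_seed(params$seed, i))
  }
  class_names <- if (length(params$focus_channels) >= 2) {
    c("left", "right")
  } else {
    c("mu_erd", "beta_erd")
  }
  epoch_set(data, labels, params$fs, montage, class_names)
}
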