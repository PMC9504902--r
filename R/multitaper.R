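
# Discrete prolate spheroidal (Slepian) tapers, computed from the classic
# symmetric tridiagonal matrix whose top eigenvectors are the DPSS, and
# cached per (n, nw, k) because the spectral windows are reused across
# trials and folds.
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  t0 <- 0:(n - 1)
  W <- nw / n
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  dpss_cache[[key]] <- tapers
  tapers
}

#' Sliding-window multitaper PSD features
#'
#' Log band power from a multitaper (DPSS) spectral estimate in sliding
#' windows over each trial: window length 1 s shifted every 62.5 ms by
#' default, 3 tapers at time-bandwidth 2, averaged into 2-Hz frequency bins
#' over 4--48 Hz. One feature row per (trial, window) pair; one column per
#' (component-or-channel, frequency-bin) pair.
#'
#' @param x An [epoch_set()], the component-space output of [apply_csp()],
#'   or a `trials x components x samples` array.
#' @param fs Sampling rate (taken from `x` when available).
#' @param win,step Window length and shift, seconds.
#' @param fmin,fmax,bin_width Frequency grid, Hz; bins are `[lo, lo + width)`.
#' @param nw Time-bandwidth product of the tapers.
#' @param k Number of tapers.
#' @return A tibble with columns `trial`, `window`, `time` (window centre,
#'   s) and one log-power column per feature, with attributes
#'   `feature_info` (tibble mapping columns to component and band) and
#'   `trial_labels` (when `x` carries labels).
#' @export
multitaper_psd <- function(x, fs = NULL, win = 1, step = 0.0625,
                           fmin = 4, fmax = 48, bin_width = 2,
                           nw = 2, k = 3) {
  comp_names <- NULL
  labels <- NULL
  if (inherits(x, "epoch_set")) {
    fs <- x$fs; comp_names <- x$montage$names; labels <- x$labels
    x <- x$data
  } else if (inherits(x, "csp_epochs")) {
    fs <- x$fs; comp_names <- x$comp_names; labels <- x$labels
    x <- x$data
  }
  d <- dim(x)
  comp_names <- comp_names %||% paste0("ch", seq_len(d[2]))
  N <- round(win * fs)
  stepn <- round(step * fs)
  if (N > d[3]) stop("window (", N, " samples) exceeds trial length (",
                     d[3], ")", call. = FALSE)
  nwin <- (d[3] - N) %/% stepn + 1L
  tapers <- dpss_tapers(N, nw, k)
  freqs <- (0:(N - 1)) * fs / N
  lo <- seq(fmin, fmax - bin_width, by = bin_width)
  bin_idx <- lapply(lo, function(l) which(freqs >= l & freqs < l + bin_width))
  nbins <- length(lo)

  # The DFT is only needed at the in-band frequency indices, so the tapered
  # transform of every window is two real matrix products against
  # precomputed taper-modulated cosine/sine bases (fast under BLAS).
  kf <- sort(unique(unlist(bin_idx)))
  t0 <- seq_len(N) - 1L
  Rcos <- NULL; Rsin <- NULL
  for (j in seq_len(k)) {
    ang <- outer((kf - 1L) * 2 * pi / N, t0)    # freq index kf is 1-based
    Rcos <- rbind(Rcos, cos(ang) * rep(tapers[, j], each = length(kf)))
    Rsin <- rbind(Rsin, sin(ang) * rep(tapers[, j], each = length(kf)))
  }
  nf <- length(kf)
  binm <- matrix(0, nbins, nf)
  for (b in seq_len(nbins)) {
    hit <- match(bin_idx[[b]], kf)
    binm[b, hit] <- 1 / length(hit)
  }

  perm <- aperm(x, c(3, 2, 1))                       # samples x comp x trial
  dim(perm) <- c(d[3], d[2] * d[1])
  core <- psd_core(perm, N, stepn, nwin, Rcos, Rsin, binm, k)
  # core rows are (bin, window); reorder to rows (window, trial) x
  # columns (bin, component)
  dim(core) <- c(nbins, nwin, d[2], d[1])
  out <- aperm(core, c(2, 4, 1, 3))
  dim(out) <- c(nwin * d[1], nbins * d[2])
  colnames(out) <- paste0(rep(comp_names, each = nbins), "_",
                          rep(lo, d[2]), "Hz")
  res <- tibble::tibble(
    trial = rep(seq_len(d[1]), each = nwin),
    window = rep(seq_len(nwin), d[1]),
    time = (rep(seq_len(nwin), d[1]) - 1L) * step + win / 2
  )
  res <- tibble::as_tibble(cbind(res, tibble::as_tibble(out)))
  attr(res, "feature_info") <- tibble::tibble(
    column = colnames(out),
    component = rep(comp_names, each = nbins),
    f_lo = rep(lo, d[2]), f_hi = rep(lo, d[2]) + bin_width
  )
  attr(res, "trial_labels") <- labels
  res
}

# Strip index columns from a feature tibble -> plain numeric matrix.
feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  drop_cols <- intersect(c("trial", "window", "time"), names(features))
  as.matrix(features[, setdiff(names(features), drop_cols), drop = FALSE])
}

# Expand per-trial labels to per-row labels of a feature tibble.
row_labels <- function(features, trial_labels = NULL) {
  trial_labels <- trial_labels %||% attr(features, "trial_labels")
  trial_labels[features$trial]
}
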