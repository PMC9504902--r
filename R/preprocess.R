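#' Preprocessing configuration
#'
#' @param target_fs Target sampling rate, Hz.
#' @param epoch_window `(start, end)` in seconds relative to the cue;
#'   half-open `[start, end)`, sample index `floor(t * fs)`.
#' @param standardize Apply per-channel standardization (training-split
#'   statistics) before network training.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(target_fs = 512, epoch_window = c(0, 2),
                           standardize = TRUE) {
  if (epoch_window[2] <= epoch_window[1]) {
    stop("epoch window end must exceed start", call. = FALSE)
  }
  structure(list(target_fs = target_fs, epoch_window = epoch_window,
                 standardize = standardize), class = "preproc_config")
}

#' Downsample a recording or epoch set
#'
#' Polyphase anti-aliased resampling (FIR) of every channel. For an
#' [eeg_recording()], event sample indices are rescaled to the new rate.
#'
#' @param x An [epoch_set()] or [eeg_recording()].
#' @param target_fs Target rate in Hz; must not exceed the current rate.
#' @return The same kind of object at `target_fs`.
#' @export
downsample <- function(x, target_fs) {
  UseMethod("downsample")
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

resample_rows <- function(m, fs, target_fs) {
  # rational ratio p/q from integer-valued rates
  p <- round(target_fs * 1000)
  q <- round(fs * 1000)
  g <- gcd(p, q)
  pq <- c(p / g, q / g)
  n_out <- round(ncol(m) * target_fs / fs)
  out <- matrix(0, nrow(m), n_out)
  for (i in seq_len(nrow(m))) {
    y <- signal::resample(m[i, ], pq[1], pq[2])
    out[i, ] <- y[seq_len(n_out)]
  }
  out
}

#' @export
downsample.eeg_recording <- function(x, target_fs) {
  if (target_fs > x$fs) stop("target_fs exceeds the sampling rate",
                             call. = FALSE)
  if (target_fs == x$fs) return(x)
  data <- resample_rows(x$data, x$fs, target_fs)
  ev <- x$events
  ev$sample <- pmax(1L, floor((ev$sample - 1) * target_fs / x$fs) + 1L)
  eeg_recording(data, target_fs, ev, x$montage, x$class_names)
}

#' @export
downsample.epoch_set <- function(x, target_fs) {
  if (target_fs > x$fs) stop("target_fs exceeds the sampling rate",
                             call. = FALSE)
  if (target_fs == x$fs) return(x)
  d <- dim(x$data)
  n_out <- round(d[3] * target_fs / x$fs)
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (i in seq_len(d[1])) {
    out[i, , ] <- resample_rows(x$data[i, , , drop = TRUE], x$fs, target_fs)
  }
  epoch_set(out, x$labels, target_fs, x$montage, x$class_names)
}

#' Cut cue-locked epochs out of a continuous recording
#'
#' The epoch window is half-open `[start, end)` seconds relative to each
#' event's cue sample; trials whose window falls outside the recording are
#' dropped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preproc_config()]; only `epoch_window` is used.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, cfg = preproc_config()) {
  w <- cfg$epoch_window
  offs0 <- floor(w[1] * rec$fs)
  n_samp <- round(rec$fs * (w[2] - w[1]))
  keep <- logical(nrow(rec$events))
  for (i in seq_len(nrow(rec$events))) {
    s0 <- rec$events$sample[i] + offs0
    keep[i] <- s0 >= 1 && (s0 + n_samp - 1) <= ncol(rec$data)
  }
  if (!any(keep)) stop("all epochs fall outside the recording", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " epoch(s) out of bounds; dropped", call. = FALSE)
  }
  ev <- rec$events[keep, , drop = FALSE]
  data <- array(0, dim = c(nrow(ev), nrow(rec$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    s0 <- ev$sample[i] + offs0
    data[i, , ] <- rec$data[, s0:(s0 + n_samp - 1)]
  }
  epoch_set(data, ev$label, rec$fs, rec$montage, rec$class_names)
}

#' Small-Laplacian spatial filter
#'
#' Subtracts, at every time point, the mean amplitude over the nearest four
#' orthogonal electrodes from each channel. Edge channels with `k < 4`
#' neighbours average over the `k` available ones; a channel with no
#' neighbours is passed through unchanged.
#'
#' @param x An [epoch_set()] or [eeg_recording()].
#' @param montage Montage supplying the neighbour structure; defaults to the
#'   object's own montage.
#' @return The same kind of object, spatially filtered.
#' @export
small_laplacian <- function(x, montage = NULL) {
  montage <- montage %||% x$montage
  L <- laplacian_matrix(montage)
  if (inherits(x, "eeg_recording")) {
    out <- x
    out$data <- L %*% x$data
    return(out)
  }
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  out <- x$data
  for (i in seq_len(d[1])) {
    out[i, , ] <- L %*% x$data[i, , , drop = TRUE]
  }
  epoch_set(out, x$labels, x$fs, x$montage, x$class_names)
}

laplacian_matrix <- function(montage) {
  n <- length(montage$names)
  L <- diag(n)
  for (c in seq_len(n)) {
    nb <- montage$neighbors[[c]]
    if (length(nb) == 0) next   # isolated channel: identity row
    L[c, nb] <- L[c, nb] - 1 / length(nb)
  }
  L
}

#' Per-channel standardization
#'
#' Centres and scales each channel using statistics pooled over trials and
#' samples. When `stats` is supplied (computed on a training split) it is
#' applied verbatim, which keeps train/test separation honest; otherwise the
#' statistics are computed from `x` itself and attached to the result as
#' attribute `"scaling"`. Channels with zero variance are left unscaled
#' (sd treated as 1) with a warning.
#'
#' @param x An [epoch_set()].
#' @param stats Optional list with per-channel `mean` and `sd` vectors.
#' @return A standardized [epoch_set()] with attribute `"scaling"`.
#' @export
standardize <- function(x, stats = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  if (is.null(stats)) {
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2])
    mu <- rowMeans(flat)
    sd <- sqrt(rowMeans((flat - mu)^2))
    if (any(sd == 0)) {
      warning("channel(s) with zero variance left unscaled", call. = FALSE)
      sd[sd == 0] <- 1
    }
    stats <- list(mean = mu, sd = sd)
  }
  out <- x$data
  for (ch in seq_len(d[2])) {
    out[, ch, ] <- (x$data[, ch, ] - stats$mean[ch]) / stats$sd[ch]
  }
  res <- epoch_set(out, x$labels, x$fs, x$montage, x$class_names)
  attr(res, "scaling") <- stats
  res
}
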