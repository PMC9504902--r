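#' Epoched EEG container
#'
#' Bundles a `trials x channels x samples` numeric array with per-trial class
#' labels, the sampling rate and the montage. This is the interchange object
#' every decoder in the package consumes.
#'
#' @param data Numeric array, `trials x channels x samples`, microvolt scale.
#' @param labels Integer vector of class labels in `{0, 1}`, one per trial.
#' @param fs Sampling rate in Hz.
#' @param montage A [generate_montage()] object matching the channel axis.
#' @param class_names Length-2 character vector naming classes 0 and 1.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, montage,
                      class_names = c("class0", "class1")) {
  if (length(dim(data)) != 3L) {
    stop("data must be a trials x channels x samples array", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1]) {
    stop("label count (", length(labels), ") must equal trial count (",
         dim(data)[1], ")", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("data contains non-finite values", call. = FALSE)
  }
  if (!inherits(montage, "montage")) stop("montage must be a <montage>",
                                          call. = FALSE)
  if (dim(data)[2] != length(montage$names)) {
    stop("channel axis (", dim(data)[2], ") does not match montage (",
         length(montage$names), " channels)", call. = FALSE)
  }
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         montage = montage, class_names = class_names),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  tab <- table(factor(x$labels, levels = 0:1, labels = x$class_names))
  cat("  classes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

subset_epochs <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs, x$montage,
            x$class_names)
}

#' Continuous multichannel recording with event markers
#'
#' @param data Numeric matrix, `channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with columns `sample` (1-based cue sample index)
#'   and `label` (0/1).
#' @param montage A [generate_montage()] object.
#' @param class_names Length-2 character vector.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, events, montage,
                          class_names = c("class0", "class1")) {
  if (!is.matrix(data)) stop("data must be a channels x samples matrix",
                             call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  events <- as.data.frame(events)
  if (any(events$sample < 1) || any(events$sample > ncol(data))) {
    stop("event sample indices out of bounds", call. = FALSE)
  }
  structure(
    list(data = data, fs = as.numeric(fs), events = events,
         montage = montage, class_names = class_names),
    class = "eeg_recording"
  )
}
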