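#' Write an epoch set to a plain-text on-disk container
#'
#' The container is a directory holding `data.tsv` (one row per
#' trial-channel pair, samples across columns, written with 17 significant
#' digits so doubles round-trip bit-exactly), `labels.txt` (one label per
#' trial) and `meta.json` (sampling rate, channel names, class names, array
#' dimensions and row-order convention).
#'
#' @param x An [epoch_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(x, dir) {
  stopifnot(inherits(x, "epoch_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(x$data)
  # rows ordered trial-major: (trial 1 ch 1..C), (trial 2 ch 1..C), ...
  m <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, file.path(dir, "data.tsv"))
  writeLines(as.character(x$labels), file.path(dir, "labels.txt"))
  meta <- list(
    fs = x$fs,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    channel_names = x$montage$names,
    class_names = x$class_names,
    montage_layout = length(x$montage$names),
    row_order = "trial-major: row index = (trial-1)*n_channels + channel"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir Container directory.
#' @return An [epoch_set()].
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "data.tsv"))
  m <- matrix(scan(text = lines, what = numeric(), sep = "\t", quiet = TRUE),
              nrow = length(lines), byrow = TRUE)
  data <- aperm(array(t(m), dim = c(meta$n_samples, meta$n_channels,
                                    meta$n_trials)), c(3, 2, 1))
  labels <- as.integer(readLines(file.path(dir, "labels.txt")))
  montage <- generate_montage(meta$montage_layout)
  if (!identical(montage$names, meta$channel_names)) {
    stop("channel names in container do not match the ", meta$montage_layout,
         "-channel montage", call. = FALSE)
  }
  epoch_set(data, labels, meta$fs, montage, meta$class_names)
}
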