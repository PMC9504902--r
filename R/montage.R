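#' Standard schematic EEG montages
#'
#' Builds a schematic 10/20-derived montage on a unit head circle. Channels
#' are arranged on a rectangular grid of sagittal rows (Fp, AF, F, FC, C, CP,
#' P, PO, O) and lateral columns (z at the midline, odd numbers left, even
#' numbers right), which is the geometry the small-Laplacian derivation and
#' the topography renderer rely on. Every layout contains C3, Cz and C4 over
#' the sensorimotor strip; left/right channel pairs are mirror-symmetric
#' about the midline.
#'
#' Neighbours are the nearest four *orthogonal* electrodes: the adjacent
#' occupied column within the same row (left/right) and the adjacent occupied
#' row at the same lateral position (front/back). Edge channels keep fewer
#' than four neighbours.
#'
#' @param layout Channel count of the layout: 16, 32 or 64.
#' @return An object of class `montage`: a list with `names` (character),
#'   `pos` (n x 2 matrix of x/y coordinates, head radius 1), and `neighbors`
#'   (list of integer vectors indexing `names`).
#' @examples
#' m <- generate_montage(32)
#' m$names[m$neighbors[[match("C3", m$names)]]]
#' @export
generate_montage <- function(layout = 32) {
  layout <- as.integer(layout)
  rows <- switch(as.character(layout),
    "16" = list(
      F  = c("F3", "Fz", "F4"),
      FC = c("FC3", "FC1", "FCz", "FC2", "FC4"),
      C  = c("C3", "C1", "Cz", "C2", "C4"),
      CP = c("CP3", "CPz", "CP4")
    ),
    "32" = list(
      Fp = c("Fp1", "Fpz", "Fp2"),
      F  = c("F7", "F3", "Fz", "F4", "F8"),
      FC = c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6"),
      C  = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6"),
      CP = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"),
      P  = c("P3", "Pz", "P4")
    ),
    "64" = list(
      Fp = c("Fp1", "Fpz", "Fp2"),
      AF = c("AF7", "AF3", "AFz", "AF4", "AF8"),
      F  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
      FC = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
      C  = c("T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "T10"),
      CP = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
      P  = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
      PO = c("PO7", "PO3", "POz", "PO4", "PO8"),
      O  = c("O1", "Oz", "O2", "Iz")
    ),
    stop("unknown montage layout: ", layout,
         " (supported layouts: 16, 32, 64 channels)", call. = FALSE)
  )

  row_y <- c(Fp = 0.82, AF = 0.62, F = 0.42, FC = 0.21, C = 0,
             CP = -0.21, P = -0.42, PO = -0.62, O = -0.82)

  names_all <- character(0)
  pos <- NULL
  row_id <- integer(0)
  for (r in seq_along(rows)) {
    labs <- rows[[r]]
    y <- row_y[[names(rows)[r]]]
    x <- vapply(labs, label_x, numeric(1))
    # Iz sits behind Oz on the midline
    y_adj <- rep(y, length(labs))
    y_adj[labs == "Iz"] <- -0.95
    names_all <- c(names_all, labs)
    pos <- rbind(pos, cbind(x, y_adj))
    row_id <- c(row_id, rep(r, length(labs)))
  }
  dimnames(pos) <- list(names_all, c("x", "y"))

  neighbors <- lapply(seq_along(names_all), function(i) {
    nb <- integer(0)
    same_row <- which(row_id == row_id[i] & seq_along(row_id) != i)
    left <- same_row[pos[same_row, 1] < pos[i, 1]]
    right <- same_row[pos[same_row, 1] > pos[i, 1]]
    if (length(left)) nb <- c(nb, left[which.max(pos[left, 1])])
    if (length(right)) nb <- c(nb, right[which.min(pos[right, 1])])
    same_col <- which(abs(pos[, 1] - pos[i, 1]) < 1e-9 & seq_along(row_id) != i)
    front <- same_col[pos[same_col, 2] > pos[i, 2]]
    back <- same_col[pos[same_col, 2] < pos[i, 2]]
    if (length(front)) nb <- c(nb, front[which.min(pos[front, 2])])
    if (length(back)) nb <- c(nb, back[which.max(pos[back, 2])])
    sort(nb)
  })

  structure(
    list(names = names_all, pos = pos, neighbors = neighbors),
    class = "montage"
  )
}

# Lateral coordinate from a 10/20-style label suffix: z = midline, odd = left,
# even = right; T7/T8 occupy the "7"/"8" positions of the C row, T9/T10 lie
# further lateral.
label_x <- function(lab) {
  if (lab %in% c("T7", "FT7", "TP7")) return(-0.72)
  if (lab %in% c("T8", "FT8", "TP8")) return(0.72)
  if (lab == "T9") return(-0.9)
  if (lab == "T10") return(0.9)
  suf <- sub("^[A-Za-z]+", "", lab)
  if (suf == "z" || suf == "") return(0)
  k <- as.integer(suf)
  step <- c(`1` = 0.18, `2` = 0.18, `3` = 0.36, `4` = 0.36,
            `5` = 0.54, `6` = 0.54, `7` = 0.72, `8` = 0.72)
  sign <- if (k %% 2 == 1) -1 else 1
  sign * step[[as.character(k)]]
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$names), " channels: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Look up channel indices by label
#'
#' @param montage A `montage`.
#' @param labels Character vector of channel labels.
#' @return Integer indices into `montage$names`.
#' @export
channel_index <- function(montage, labels) {
  idx <- match(labels, montage$names)
  if (anyNA(idx)) {
    stop("channel(s) not in montage: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
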