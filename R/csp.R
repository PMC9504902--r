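#' Common spatial patterns via generalized eigendecomposition
#'
#' Finds spatial filters `w` extremizing the Rayleigh quotient
#' `J(w) = (w' S1 w) / (w' S2 w)` of the two class covariances, solved as
#' the generalized eigenproblem `S1 w = lambda S2 w` by whitening `S2` and
#' diagonalizing the whitened `S1`. Each trial's covariance `X X'` is
#' normalized by its trace before class-averaging. Filters are sorted by
#' descending eigenvalue and the top and bottom `m` retained (the top ones
#' maximize class-1 variance, the bottom ones class-2 variance).
#'
#' @param epochs An [epoch_set()] (or `trials x channels x samples` array).
#' @param labels 0/1 labels; defaults to `epochs$labels`.
#' @param m Filter pairs retained per side.
#' @param ridge Relative ridge added to a rank-deficient class covariance.
#' @return An object of class `csp_model`: `W` (`2m x channels` filter
#'   matrix, rows sorted by descending eigenvalue), `eigenvalues` (all
#'   channels), `selected` (indices of the retained eigenvalues).
#' @export
fit_csp <- function(epochs, labels = NULL, m = 3, ridge = 1e-8) {
  if (inherits(epochs, "epoch_set")) {
    labels <- labels %||% epochs$labels
    epochs <- epochs$data
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  S1 <- class_covariance(epochs, labels == 0)
  S2 <- class_covariance(epochs, labels == 1)
  csp_from_cov(S1, S2, m = m, ridge = ridge)
}

class_covariance <- function(data, sel) {
  class_cov_core(data, as.integer(which(sel)))
}

#' CSP from class covariance matrices
#'
#' @param S1,S2 Symmetric positive (semi-)definite class covariances.
#' @param m Filter pairs per side; `m = NULL` keeps all filters.
#' @param ridge Relative ridge for rank-deficient `S2`.
#' @return A `csp_model`; see [fit_csp()].
#' @export
csp_from_cov <- function(S1, S2, m = 3, ridge = 1e-8) {
  n <- nrow(S1)
  e2 <- eigen(S2, symmetric = TRUE)
  tol <- max(e2$values) * 1e-10
  if (any(e2$values < tol)) {
    S2 <- S2 + diag(ridge * sum(diag(S2)), n)
    message("rank-deficient covariance; ridge-regularized")
    e2 <- eigen(S2, symmetric = TRUE)
  }
  Wh <- diag(1 / sqrt(e2$values)) %*% t(e2$vectors)   # whitens S2
  ew <- eigen(Wh %*% S1 %*% t(Wh), symmetric = TRUE)
  W_all <- t(ew$vectors) %*% Wh                       # rows: filters
  lambda <- ew$values                                 # descending
  selected <- if (is.null(m) || 2 * m >= n) {
    seq_len(n)
  } else {
    c(seq_len(m), (n - m + 1L):n)
  }
  structure(list(W = W_all[selected, , drop = FALSE],
                 eigenvalues = lambda, selected = selected),
            class = "csp_model")
}

#' Rayleigh quotient of a spatial filter
#'
#' `J(w) = (w' S1 w) / (w' S2 w)`; for a generalized eigenvector this equals
#' its eigenvalue.
#'
#' @param w Filter vector.
#' @param S1,S2 Class covariances.
#' @return Scalar quotient.
#' @export
csp_objective <- function(w, S1, S2) {
  drop((w %*% S1 %*% w) / (w %*% S2 %*% w))
}

#' Project epochs through CSP filters
#'
#' @param model A `csp_model`.
#' @param epochs An [epoch_set()] or array; channel count must match.
#' @return An [epoch_set()]-like object in component space (`trials x
#'   n_filters x samples`); component "channels" are named `CSP1, CSP2, ...`
#'   and the montage is dropped.
#' @export
apply_csp <- function(model, epochs) {
  meta <- NULL
  if (inherits(epochs, "epoch_set")) {
    meta <- epochs[c("labels", "fs", "class_names")]
    epochs <- epochs$data
  }
  d <- dim(epochs)
  if (d[2] != ncol(model$W)) {
    stop("channel count (", d[2], ") does not match CSP filters (",
         ncol(model$W), ")", call. = FALSE)
  }
  flat <- aperm(epochs, c(2, 3, 1))
  dim(flat) <- c(d[2], d[3] * d[1])
  proj <- model$W %*% flat
  dim(proj) <- c(nrow(model$W), d[3], d[1])
  out <- aperm(proj, c(3, 1, 2))
  structure(list(data = out, labels = meta$labels, fs = meta$fs,
                 comp_names = paste0("CSP", seq_len(nrow(model$W))),
                 class_names = meta$class_names),
            class = "csp_epochs")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> ", nrow(x$W), " filters over ", ncol(x$W), " channels; ",
      "eigenvalue range ", signif(min(x$eigenvalues), 3), " .. ",
      signif(max(x$eigenvalues), 3), "\n", sep = "")
  invisible(x)
}
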