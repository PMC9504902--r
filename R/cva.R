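#' Canonical discriminant ranking of features
#'
#' Two-class canonical variate analysis. Per feature, the discriminant
#' power is the diagonal Fisher ratio: between-class scatter of the feature
#' divided by its pooled within-class scatter. Features with zero
#' within-class variance get power 0. The full canonical direction (the
#' Fisher discriminant, which for two classes is the single canonical
#' variate) is also computed on request.
#'
#' @param features Feature tibble from [multitaper_psd()] or a plain
#'   row-per-observation matrix.
#' @param labels 0/1 label per row (per (trial, window) pair for PSD
#'   features); defaults to expanding the tibble's trial labels.
#' @param direction Also compute the full Fisher discriminant direction
#'   (ridge-regularized pooled covariance inverse times the mean
#'   difference), returned as attribute `"direction"`.
#' @return A tibble with columns `feature`, `power` and `rank` (1 = most
#'   discriminant; ties broken by column order), carrying the input's
#'   `feature_info` attribute.
#' @export
cva_rank <- function(features, labels = NULL, direction = FALSE) {
  X <- feature_matrix(features)
  if (is.null(labels) && !is.null(attr(features, "trial_labels"))) {
    labels <- row_labels(features)
  }
  if (min(table(labels)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  g0 <- labels == 0
  n0 <- sum(g0); n1 <- sum(!g0)
  m0 <- colMeans(X[g0, , drop = FALSE])
  m1 <- colMeans(X[!g0, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ssw <- colSums((t(t(X[g0, , drop = FALSE]) - m0))^2) +
         colSums((t(t(X[!g0, , drop = FALSE]) - m1))^2)
  power <- ifelse(ssw > 0, ssb / ssw, 0)
  if (any(ssw == 0)) {
    message(sum(ssw == 0), " feature(s) with zero within-class variance; ",
            "power set to 0")
  }
  res <- tibble::tibble(
    feature = colnames(X) %||% paste0("f", seq_along(power)),
    power = unname(power),
    rank = rank(-power, ties.method = "first")
  )
  if (direction) {
    Sw <- (crossprod(t(t(X[g0, , drop = FALSE]) - m0)) +
           crossprod(t(t(X[!g0, , drop = FALSE]) - m1))) / (n0 + n1 - 2)
    ridge <- 1e-8 * mean(diag(Sw))
    attr(res, "direction") <-
      drop(solve(Sw + diag(ridge, ncol(X)), m1 - m0))
  }
  attr(res, "feature_info") <- attr(features, "feature_info")
  res
}

#' Grid search over the number of retained features
#'
#' Features are ranked by discriminant power on the training split; for each
#' candidate count the top-ranked features feed a linear SVM and the
#' validation error is recorded. The best count minimizes validation error,
#' ties resolved toward the smaller count.
#'
#' @param train_features,train_labels Training rows and 0/1 row labels.
#' @param val_features,val_labels Validation rows and labels.
#' @param grid Candidate feature counts (each at most the total available).
#' @param cost SVM regularization constant.
#' @return `list(best, curve)`: the chosen count and a tibble
#'   `(n_features, val_error)` for plotting the selection curve.
#' @export
select_feature_count <- function(train_features, train_labels,
                                 val_features, val_labels,
                                 grid, cost = 1) {
  if (length(grid) == 0) stop("empty feature-count grid", call. = FALSE)
  Xt <- feature_matrix(train_features)
  Xv <- feature_matrix(val_features)
  if (any(grid > ncol(Xt))) {
    stop("grid contains counts above the number of features", call. = FALSE)
  }
  ranking <- cva_rank(train_features, train_labels)
  ord <- order(ranking$rank)
  errs <- vapply(grid, function(nf) {
    sel <- ord[seq_len(nf)]
    fit <- train_svm(Xt[, sel, drop = FALSE], train_labels, cost = cost)
    pred <- predict(fit, Xv[, sel, drop = FALSE], type = "class")
    mean(pred != val_labels)
  }, numeric(1))
  ord_grid <- order(errs, grid)      # ties -> smaller count
  list(best = grid[ord_grid[1]],
       curve = tibble::tibble(n_features = grid, val_error = errs))
}

#' Channel-space topography of discriminant power
#'
#' Averages per-feature discriminant power across the frequency bins of each
#' channel. Meaningful when the ranking was computed on channel-space
#' features (CSP off), which is the interpretable mode for scalp maps.
#'
#' @param ranking Output of [cva_rank()] carrying `feature_info`.
#' @param montage The montage whose channels the features cover.
#' @return Named numeric vector of non-negative per-channel scores, aligned
#'   with `montage$names` (channels without features score 0).
#' @export
cva_topography <- function(ranking, montage) {
  info <- attr(ranking, "feature_info")
  if (is.null(info)) stop("ranking carries no feature_info", call. = FALSE)
  scores <- stats::setNames(numeric(length(montage$names)), montage$names)
  agg <- tapply(ranking$power, info$component, mean)
  hit <- intersect(names(agg), names(scores))
  scores[hit] <- agg[hit]
  scores
}
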