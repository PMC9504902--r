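#' Exact binomial chance level
#'
#' The smallest accuracy `k/n` whose one-sided binomial tail probability
#' under random guessing, `P(Binomial(n, 1/n_classes) >= k)`, does not
#' exceed `alpha`. The tail is an exact sum over the probability mass
#' function; no normal approximation is used.
#'
#' @param n_trials Number of classified trials.
#' @param n_classes Number of classes (guessing probability `1/n_classes`).
#' @param alpha Significance level.
#' @return Accuracy threshold in `[0, 1]`.
#' @export
binomial_chance_level <- function(n_trials, n_classes = 2, alpha = 0.05) {
  stopifnot_scalar_count(n_trials, "n_trials")
  stopifnot(alpha > 0, alpha <= 1)
  p <- 1 / n_classes
  pmf <- stats::dbinom(0:n_trials, n_trials, p)
  tail <- rev(cumsum(rev(pmf)))     # tail[k + 1] = P(X >= k)
  k <- which(tail <= alpha + 1e-12)[1] - 1L
  if (is.na(k)) k <- n_trials + 1L  # alpha too small for any k (n tiny)
  k / n_trials
}

#' Stratified k-fold cross-validation of a decoder
#'
#' Trials of each class are shuffled by seed and dealt round-robin into `k`
#' folds. All fitting — standardization statistics, CSP filters,
#' discriminant ranking, feature-count selection, SVM or network training —
#' happens inside each training fold only; predictions are pooled per test
#' fold.
#'
#' @param epochs An [epoch_set()].
#' @param spec A [decoder_pipeline()].
#' @param k Number of folds; must not exceed the smaller class count.
#' @param seed Seed controlling fold assignment and per-fold fits.
#' @param alpha Significance level for the reported chance threshold.
#' @return An object of class `decoding_result`: tibble of per-fold
#'   accuracies plus mean, sd, the exact binomial chance level for the
#'   total trial count, and the run configuration.
#' @export
kfold_cv <- function(epochs, spec, k = 10, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "decoder_spec"))
  n <- n_trials(epochs)
  counts <- table(epochs$labels)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the smaller class count (", min(counts), ")",
         call. = FALSE)
  }
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(epochs$labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    fit <- fit_decoder(spec, subset_epochs(epochs, -test_idx),
                       seed = child_seed(seed, f))
    pred <- predict(fit, subset_epochs(epochs, test_idx))
    folds[[f]] <- c(fold = f, n_test = length(test_idx),
                    accuracy = mean(pred == epochs$labels[test_idx]))
  }
  tab <- tibble::as_tibble(do.call(rbind, folds))
  structure(
    list(folds = tab,
         mean_accuracy = mean(tab$accuracy),
         sd_accuracy = stats::sd(tab$accuracy),
         chance_level = binomial_chance_level(n, 2, alpha),
         model = spec$model, k = k, seed = seed, n_trials = n,
         alpha = alpha),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", x$model, ": ",
      sprintf("%.1f%% +/- %.1f%%", 100 * x$mean_accuracy,
              100 * x$sd_accuracy),
      " over ", x$k, "-fold CV (n = ", x$n_trials, ", chance ",
      sprintf("%.1f%%", 100 * x$chance_level), " at alpha = ", x$alpha,
      ")\n", sep = "")
  invisible(x)
}

#' Structured run report
#'
#' @param result A `decoding_result`.
#' @param file Optional path; when given the report is written as JSON.
#' @return The report list, invisibly when written to file.
#' @export
run_report <- function(result, file = NULL) {
  rep <- list(
    model = result$model,
    k = result$k, seed = result$seed, n_trials = result$n_trials,
    fold_accuracies = result$folds$accuracy,
    mean_accuracy = result$mean_accuracy,
    sd_accuracy = result$sd_accuracy,
    chance_level = result$chance_level, alpha = result$alpha,
    package_version = as.character(utils::packageVersion("smrdecode"))
  )
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
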