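#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold accuracies of a cross-validation run
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(model = x$model, fold = as.integer(x$folds$fold),
                 n_test = as.integer(x$folds$n_test),
                 accuracy = x$folds$accuracy)
}

#' One-row summary of a cross-validation run
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble with mean/sd accuracy, the chance level and run sizes.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(model = x$model, mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy, chance_level = x$chance_level,
                 k = x$k, n_trials = x$n_trials, seed = x$seed)
}

#' Training history of a fitted network
#'
#' @param x A `cnn_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (loss, validation error, learning
#'   rate).
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @export
tidy.mlp_fit <- function(x, ...) x$history

#' @export
glance.cnn_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)],
                 best_val_error = x$best_val_error,
                 final_lr = x$history$lr[nrow(x$history)])
}

#' @export
glance.mlp_fit <- function(x, ...) glance.cnn_fit(x, ...)

#' Tidy CSP eigenvalues
#'
#' @param x A `csp_model`.
#' @param ... Unused.
#' @return Tibble of retained filters and their generalized eigenvalues.
#' @export
tidy.csp_model <- function(x, ...) {
  tibble::tibble(filter = seq_len(nrow(x$W)),
                 eigenvalue = x$eigenvalues[x$selected])
}

#' Plot per-fold accuracies against the chance level
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$chance_level,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dotted") +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = paste0(object$model, ": ",
                                 sprintf("%.1f%%", 100 * object$mean_accuracy),
                                 " (chance ",
                                 sprintf("%.1f%%", 100 * object$chance_level),
                                 ")")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the training curve of a fitted network
#'
#' @param object A `cnn_fit` or `mlp_fit`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation error per epoch.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- object$history
  df <- tibble::tibble(
    epoch = rep(h$epoch, 2),
    value = c(h$loss, h$val_error),
    metric = rep(c("training loss", "validation error"), each = nrow(h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' @export
autoplot.mlp_fit <- function(object, ...) autoplot.cnn_fit(object, ...)
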