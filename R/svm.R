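#' Linear soft-margin SVM
#'
#' Trains a linear support vector machine by solving the soft-margin dual
#' (sequential minimal optimization via libsvm) and extracts the primal
#' weight vector, bias and support-vector multipliers. The sign convention
#' is fixed so the decision value `f(x) = w'x + b` is positive for class 1.
#' A Platt-style logistic map `sigmoid(a f(x) + c)`, fitted on the training
#' decision values with smoothed targets, converts margins to
#' probabilities.
#'
#' @param x Feature matrix (rows = observations) or feature tibble.
#' @param labels Labels in `{0, 1}` or `{-1, +1}`; both classes required.
#' @param cost Soft-margin constant `C`.
#' @return An object of class `svm_model` with elements `w`, `b`, `alphas`,
#'   `cost`, `platt` (`a`, `c`).
#' @export
train_svm <- function(x, labels, cost = 1) {
  X <- feature_matrix(x)
  y <- as.integer(labels)
  y[y == 0L] <- -1L
  if (!all(y %in% c(-1L, 1L))) stop("labels must be 0/1 or -1/+1",
                                    call. = FALSE)
  if (length(unique(y)) < 2) stop("all labels equal; need two classes",
                                  call. = FALSE)
  fit <- e1071::svm(X, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  f <- drop(X %*% w) + b
  if (mean(f[y == 1]) < mean(f[y == -1])) {   # enforce f > 0 <=> class 1
    w <- -w; b <- -b
  }
  f <- drop(X %*% w) + b
  alphas <- abs(drop(fit$coefs))
  # Platt-style logistic map fitted on the training decision values by
  # maximum likelihood; on a separable set the slope saturates at the
  # solver's convergence tolerance, giving probabilities near 0/1.
  pf <- suppressWarnings(
    stats::glm((y + 1) / 2 ~ f, family = stats::binomial())
  )
  structure(list(w = w, b = b, alphas = alphas, cost = cost,
                 platt = list(a = unname(stats::coef(pf)[2]),
                              c = unname(stats::coef(pf)[1]))),
            class = "svm_model")
}

#' Decision values of a linear SVM
#'
#' @param model An `svm_model`.
#' @param x Feature matrix or tibble.
#' @return Numeric vector `w'x + b`.
#' @export
svm_decision <- function(model, x) {
  drop(feature_matrix(x) %*% model$w) + model$b
}

#' @export
predict.svm_model <- function(object, newdata,
                              type = c("class", "decision", "prob"), ...) {
  type <- match.arg(type)
  f <- svm_decision(object, newdata)
  switch(type,
    decision = f,
    class = as.integer(f > 0),
    prob = svm_probability(object, newdata)
  )
}

#' Margin-to-probability map
#'
#' Applies the fitted Platt map `sigmoid(a f(x) + c)` to decision values;
#' the result is the probability of class 1 and is monotone in `f`.
#'
#' @param model An `svm_model`.
#' @param x Feature matrix/tibble, or a numeric vector of decision values
#'   when `is_decision = TRUE`.
#' @param is_decision Interpret `x` as precomputed decision values.
#' @return Probabilities in `(0, 1)`.
#' @export
svm_probability <- function(model, x, is_decision = FALSE) {
  f <- if (is_decision) x else svm_decision(model, x)
  stats::plogis(model$platt$a * f + model$platt$c)
}

#' @export
print.svm_model <- function(x, ...) {
  cat("<svm_model> linear, ", length(x$w), " features, ",
      length(x$alphas), " support vectors, C = ", x$cost, "\n", sep = "")
  invisible(x)
}
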