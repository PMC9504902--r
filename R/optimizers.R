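#' Adam optimizer state
#'
#' First/second-moment accumulators (zero-initialized), bias-correction step
#' counter, and the hyperparameters `beta1 = 0.9`, `beta2 = 0.999`,
#' `epsilon = 1e-8`.
#'
#' @param params Named list of parameter arrays the state shadows.
#' @param alpha Learning rate.
#' @param beta1,beta2,epsilon Adam constants.
#' @return A list of class `adam_state`.
#' @export
adam_state <- function(params, alpha = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  structure(list(V = zeros, S = zeros, t = 0L, alpha = alpha,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "adam_state")
}

#' One Adam update
#'
#' Momentum and RMS accumulators are updated elementwise, bias-corrected by
#' `1 - beta^t` with the step counter incremented first, and the parameters
#' moved by `alpha * Vhat / (sqrt(Shat) + epsilon)`.
#'
#' @param params Named list of parameter arrays.
#' @param grads Matching named list of gradients.
#' @param state An [adam_state()].
#' @return `list(params, state)` after the update.
#' @export
adam_step <- function(params, grads, state) {
  if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient in Adam step", call. = FALSE)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$V[[nm]] <- state$beta1 * state$V[[nm]] + (1 - state$beta1) * g
    state$S[[nm]] <- state$beta2 * state$S[[nm]] + (1 - state$beta2) * g^2
    vhat <- state$V[[nm]] / bc1
    shat <- state$S[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      state$alpha * vhat / (sqrt(shat) + state$epsilon)
  }
  list(params = params, state = state)
}

#' RMSprop optimizer state
#'
#' Squared-gradient accumulators (zero-initialized) with decay `beta = 0.9`.
#' A small `epsilon` is added inside the square root of the update to guard
#' the first steps, where the accumulator can be arbitrarily small.
#'
#' @param params Named list of parameter arrays.
#' @param alpha Learning rate.
#' @param beta Accumulator decay.
#' @param epsilon Stabilizer inside the square root.
#' @return A list of class `rmsprop_state`.
#' @export
rmsprop_state <- function(params, alpha = 1e-4, beta = 0.9, epsilon = 1e-8) {
  zeros <- lapply(params, function(p) p * 0)
  structure(list(S = zeros, alpha = alpha, beta = beta, epsilon = epsilon),
            class = "rmsprop_state")
}

#' One RMSprop update
#'
#' `S := beta S + (1 - beta) g^2`, then
#' `W := W - alpha g / sqrt(S + epsilon)`, elementwise, for weights and
#' biases alike.
#'
#' @inheritParams adam_step
#' @param state An [rmsprop_state()].
#' @return `list(params, state)` after the update.
#' @export
rmsprop_step <- function(params, grads, state) {
  if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradient in RMSprop step", call. = FALSE)
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$S[[nm]] <- state$beta * state$S[[nm]] + (1 - state$beta) * g^2
    params[[nm]] <- params[[nm]] -
      state$alpha * g / sqrt(state$S[[nm]] + state$epsilon)
  }
  list(params = params, state = state)
}
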