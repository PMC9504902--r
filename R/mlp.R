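#' MLP architecture specification
#'
#' The perceptron baseline: flattened epochs through three rectifier hidden
#' layers (1000, 300, 80 units) and a 2-unit softmax output. Epochs are
#' flattened channel-major (channel varies slowest), i.e. the samples of
#' channel 1 come first.
#'
#' @param input_size Flattened input length `C * T`.
#' @param hidden Hidden layer sizes.
#' @param n_classes Output units.
#' @return A list of class `mlp_spec`.
#' @export
mlp_spec <- function(input_size, hidden = c(1000, 300, 80), n_classes = 2) {
  stopifnot(all(hidden > 0), input_size > 0)
  structure(list(sizes = c(as.integer(input_size), as.integer(hidden),
                           as.integer(n_classes))),
            class = "mlp_spec")
}

#' Initialize MLP parameters
#'
#' Same scheme as the CNN: zero-mean Gaussian weights with standard
#' deviation 0.01, biases set to one.
#'
#' @param spec An [mlp_spec()].
#' @param seed Integer seed.
#' @return Named list `W1, b1, ..., WL, bL`.
#' @export
init_mlp <- function(spec, seed = 1L) {
  s <- spec$sizes
  with_seed(seed, {
    params <- list()
    for (l in seq_len(length(s) - 1L)) {
      params[[paste0("W", l)]] <-
        matrix(stats::rnorm(s[l + 1] * s[l], 0, 0.01), s[l + 1], s[l])
      params[[paste0("b", l)]] <- rep(1, s[l + 1])
    }
    params
  })
}

# epochs -> (C*T) x B matrix, channel-major flattening
flatten_epochs <- function(x) {
  if (inherits(x, "epoch_set")) x <- x$data
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  d <- dim(x)
  matrix(aperm(x, c(3, 2, 1)), nrow = d[2] * d[3])
}

#' MLP forward pass
#'
#' @param params Parameters from [init_mlp()] or [train_mlp()].
#' @param batch `trials x (C*T)` matrix, a `(C*T)`-vector, an [epoch_set()],
#'   or a `trials x C x T` array (flattened channel-major).
#' @param spec An [mlp_spec()].
#' @param keep_cache Keep layer activations for the backward pass.
#' @return `trials x n_classes` matrix of softmax probabilities.
#' @export
mlp_forward <- function(params, batch, spec, keep_cache = FALSE) {
  X <- if (inherits(batch, "epoch_set") ||
           (is.array(batch) && length(dim(batch)) == 3L)) {
    flatten_epochs(batch)
  } else if (is.matrix(batch)) {
    t(batch)
  } else {
    matrix(batch, ncol = 1)
  }
  if (nrow(X) != spec$sizes[1]) {
    stop("flattened input length ", nrow(X), " does not match spec (",
         spec$sizes[1], ")", call. = FALSE)
  }
  L <- length(spec$sizes) - 1L
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- params[[paste0("W", l)]] %*% A + params[[paste0("b", l)]]
    A <- if (l < L) pmax(Z, 0) else softmax_cols(Z)
    acts[[l + 1L]] <- A
  }
  if (!keep_cache) return(t(A))
  list(probs = t(A), acts = acts)
}

#' Regularized cross-entropy loss
#'
#' Binary cross entropy of the class-1 probability plus an L2 weight-decay
#' penalty `lambda / (2 n) * sum(w^2)` over the weights only (biases are
#' not penalized). With a two-unit softmax the class-1 probability is
#' `1 - ` the class-0 probability, so the binary form is equivalent to the
#' two-class cross entropy.
#'
#' @param probs `trials x 2` probability matrix (clipped at `1e-12`).
#' @param labels 0/1 labels.
#' @param params Parameter list (for the penalty term).
#' @param lambda Regularization strength.
#' @param n Training-set size used to scale the penalty.
#' @return Scalar loss (non-negative for `lambda >= 0`).
#' @export
regularized_loss <- function(probs, labels, params = NULL, lambda = 0,
                             n = length(labels)) {
  if (n == 0) stop("n must be positive", call. = FALSE)
  a <- pmin(pmax(probs[, 2], 1e-12), 1 - 1e-12)
  y <- as.numeric(labels)
  ce <- -mean(y * log(a) + (1 - y) * log(1 - a))
  pen <- 0
  if (lambda > 0 && !is.null(params)) {
    wsum <- sum(vapply(grep("^W", names(params), value = TRUE),
                       function(nm) sum(params[[nm]]^2), numeric(1)))
    pen <- lambda / (2 * n) * wsum
  }
  ce + pen
}

# Loss and analytic gradients for a batch, including the weight-decay term
# scaled by the full training-set size n_total.
mlp_loss_grad <- function(params, spec, batch, labels, lambda = 0,
                          n_total = length(labels)) {
  fw <- mlp_forward(params, batch, spec, keep_cache = TRUE)
  B <- length(labels)
  loss <- regularized_loss(fw$probs, labels, params, lambda, n_total)
  L <- length(spec$sizes) - 1L
  Y <- matrix(0, spec$sizes[L + 1L], B)
  Y[cbind(labels + 1L, seq_len(B))] <- 1
  delta <- (t(fw$probs) - Y) / B
  grads <- list()
  for (l in rev(seq_len(L))) {
    A_prev <- fw$acts[[l]]
    gW <- tcrossprod(delta, A_prev)
    if (lambda > 0) gW <- gW + (lambda / n_total) * params[[paste0("W", l)]]
    grads[[paste0("W", l)]] <- gW
    grads[[paste0("b", l)]] <- rowSums(delta)
    if (l > 1L) {
      delta <- crossprod(params[[paste0("W", l)]], delta)
      delta[fw$acts[[l]] <= 0] <- 0
    }
  }
  list(loss = loss, grads = grads[names(params)])
}

#' Train the MLP decoder
#'
#' Mini-batch RMSprop on the L2-regularized cross entropy with early
#' stopping on validation error (the plateau/learning-rate schedule of
#' [train_config()] applies). Input epochs are expected to be
#' Laplacian-filtered and epoched; [decoder_pipeline()] wires that up.
#'
#' @param train An [epoch_set()] with both classes.
#' @param cfg A [train_config()]; `lambda` sets the weight decay.
#' @param spec Optional [mlp_spec()].
#' @return An object of class `mlp_fit`.
#' @export
train_mlp <- function(train, cfg = train_config(), spec = NULL) {
  stopifnot(inherits(train, "epoch_set"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  d <- dim(train$data)
  spec <- spec %||% mlp_spec(input_size = d[2] * d[3])
  scaling <- NULL
  if (isTRUE(cfg$standardize)) {
    train <- standardize(train)
    scaling <- attr(train, "scaling")
  }
  Xall <- flatten_epochs(train)                     # (C*T) x n
  res <- with_seed(cfg$seed, {
    sp <- val_split(train$labels, cfg$val_fraction)
    yt <- train$labels[sp$train]
    yv <- train$labels[sp$val]
    Xt <- Xall[, sp$train, drop = FALSE]
    Xv <- Xall[, sp$val, drop = FALSE]
    params <- init_mlp(spec, seed = sample.int(.Machine$integer.max, 1))
    state <- rmsprop_state(params, alpha = cfg$alpha0)
    reinit <- function() {
      p <- init_mlp(spec, seed = sample.int(.Machine$integer.max, 1))
      list(params = p, state = rmsprop_state(p, alpha = cfg$alpha0))
    }
    run_training(
      params, state, rmsprop_step,
      loss_grad = function(p, idx) {
        mlp_loss_grad(p, spec, t(Xt[, idx, drop = FALSE]), yt[idx],
                      lambda = cfg$lambda, n_total = length(yt))
      },
      val_error = function(p) {
        pr <- mlp_forward(p, t(Xv), spec)
        mean((max.col(pr) - 1L) != yv)
      },
      n_train = length(yt), cfg = cfg, reinit = reinit
    )
  })
  structure(list(params = res$params, spec = spec, history = res$history,
                 best_val_error = res$best_val_error, scaling = scaling,
                 restarts = res$restarts, config = cfg,
                 class_names = train$class_names),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "epoch_set") && !is.null(object$scaling)) {
    newdata <- standardize(newdata, stats = object$scaling)
  }
  pr <- mlp_forward(object$params, newdata, object$spec)
  colnames(pr) <- object$class_names
  if (type == "prob") pr else max.col(pr) - 1L
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat("<mlp_fit> layers ", paste(x$spec$sizes, collapse = "-"), ", ",
      nrow(x$history), " epochs, best validation error ",
      signif(x$best_val_error, 3), "\n", sep = "")
  invisible(x)
}
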