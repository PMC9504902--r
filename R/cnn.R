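#' CNN architecture specification
#'
#' The raw-EEG convolutional decoder: a spatial convolution collapsing the
#' channel axis (`conv1_kernels` kernels of shape `C x 1`, stride 1), a
#' temporal convolution (`conv2_kernels` kernels of shape
#' `conv1_kernels x conv2_len`, zero-padded so the output keeps the input
#' length), non-overlapping `1 x pool` max pooling, a dense rectifier layer
#' and a 2-unit softmax output. For a 32 x 1024 epoch the intermediate
#' shapes are (8, 1024) -> (40, 1024) -> (40, 128) -> 5120 -> 150 -> 2.
#'
#' @param n_channels Input channel count `C`.
#' @param n_samples Input epoch length `T` in samples.
#' @param conv1_kernels,conv2_kernels,conv2_len,pool,dense,n_classes
#'   Architecture sizes.
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(n_channels = 32, n_samples = 1024, conv1_kernels = 8,
                     conv2_kernels = 40, conv2_len = 16, pool = 8,
                     dense = 150, n_classes = 2) {
  pooled <- n_samples %/% pool
  if (pooled < 1) stop("epoch too short for the pooling kernel",
                       call. = FALSE)
  structure(
    list(C = as.integer(n_channels), T = as.integer(n_samples),
         K1 = as.integer(conv1_kernels), K2 = as.integer(conv2_kernels),
         klen = as.integer(conv2_len), pool = as.integer(pool),
         pooled = as.integer(pooled), dense = as.integer(dense),
         n_classes = as.integer(n_classes),
         flat = as.integer(conv2_kernels * pooled),
         padl = as.integer((conv2_len - 1) %/% 2)),
    class = "cnn_spec"
  )
}

#' Initialize CNN parameters
#'
#' Weights are drawn from a zero-mean Gaussian with standard deviation 0.01;
#' all biases are set to the constant one, which gives the rectifier units
#' positive inputs early in training.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed; initialization is deterministic given the seed.
#' @return Named list of weight/bias arrays (`W1`, `b1`, ..., `W4`, `b4`).
#' @export
init_cnn <- function(spec, seed = 1L) {
  with_seed(seed, {
    list(
      W1 = matrix(stats::rnorm(spec$K1 * spec$C, 0, 0.01), spec$K1, spec$C),
      b1 = rep(1, spec$K1),
      W2 = array(stats::rnorm(spec$K2 * spec$K1 * spec$klen, 0, 0.01),
                 dim = c(spec$K2, spec$K1, spec$klen)),
      b2 = rep(1, spec$K2),
      W3 = matrix(stats::rnorm(spec$dense * spec$flat, 0, 0.01),
                  spec$dense, spec$flat),
      b3 = rep(1, spec$dense),
      W4 = matrix(stats::rnorm(spec$n_classes * spec$dense, 0, 0.01),
                  spec$n_classes, spec$dense),
      b4 = rep(1, spec$n_classes)
    )
  })
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# batch: B x C x T array -> C x (T*B) matrix (time fastest, then trial)
batch_to_mat <- function(batch) {
  d <- dim(batch)
  matrix(aperm(batch, c(2, 3, 1)), nrow = d[2])
}

#' CNN forward pass
#'
#' @param params Parameters from [init_cnn()] or [train_cnn()].
#' @param batch Numeric array `trials x C x T` (a single `C x T` matrix is
#'   promoted to a one-trial batch), or an [epoch_set()].
#' @param spec A [cnn_spec()] matching `params`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return `trials x n_classes` matrix of softmax probabilities; with
#'   `keep_cache = TRUE`, a list `(probs, cache)`.
#' @export
cnn_forward <- function(params, batch, spec, keep_cache = FALSE) {
  if (inherits(batch, "epoch_set")) batch <- batch$data
  if (is.matrix(batch)) batch <- array(batch, dim = c(1, dim(batch)))
  d <- dim(batch)
  if (d[2] != spec$C || d[3] != spec$T) {
    stop("batch shape (", d[2], " x ", d[3], ") does not match spec (",
         spec$C, " x ", spec$T, ")", call. = FALSE)
  }
  B <- d[1]
  Xmat <- batch_to_mat(batch)                              # C x (T*B)
  A1 <- pmax(params$W1 %*% Xmat + params$b1, 0)            # K1 x (T*B)
  M <- im2col_batch(A1, spec$K1, spec$T, B, spec$klen, spec$padl)
  W2mat <- matrix(params$W2, spec$K2, spec$K1 * spec$klen)
  A2 <- pmax(W2mat %*% M + params$b2, 0)                   # K2 x (T*B)
  pl <- maxpool_fwd(A2, spec$K2, spec$T, B, spec$pool)
  Fmat <- matrix(pl$out, spec$flat, B)                     # component-fastest
  H <- pmax(params$W3 %*% Fmat + params$b3, 0)
  logits <- params$W4 %*% H + params$b4
  probs <- softmax_cols(logits)
  if (!keep_cache) return(t(probs))
  list(probs = t(probs),
       cache = list(Xmat = Xmat, A1 = A1, M = M, A2 = A2, idx = pl$idx,
                    Fmat = Fmat, H = H, probs = probs, B = B))
}

# Loss (mean cross entropy) and analytic gradients for one batch.
cnn_loss_grad <- function(params, spec, batch, labels) {
  fw <- cnn_forward(params, batch, spec, keep_cache = TRUE)
  cc <- fw$cache
  B <- cc$B
  Y <- matrix(0, spec$n_classes, B)
  Y[cbind(labels + 1L, seq_len(B))] <- 1
  p_true <- pmax(cc$probs[cbind(labels + 1L, seq_len(B))], 1e-12)
  loss <- -mean(log(p_true))

  dlogits <- (cc$probs - Y) / B                            # n_classes x B
  dW4 <- tcrossprod(dlogits, cc$H)
  db4 <- rowSums(dlogits)
  dH <- crossprod(params$W4, dlogits)
  dH[cc$H <= 0] <- 0
  dW3 <- tcrossprod(dH, cc$Fmat)
  db3 <- rowSums(dH)
  dF <- crossprod(params$W3, dH)
  dP <- matrix(dF, spec$K2, spec$pooled * B)
  dA2 <- maxpool_bwd(dP, cc$idx, spec$K2, spec$T, B)
  dA2[cc$A2 <= 0] <- 0
  W2mat <- matrix(params$W2, spec$K2, spec$K1 * spec$klen)
  dW2mat <- tcrossprod(dA2, cc$M)
  db2 <- rowSums(dA2)
  dM <- crossprod(W2mat, dA2)
  dA1 <- matrix(col2im_batch(dM, spec$K1, spec$T, B, spec$klen, spec$padl),
                spec$K1, spec$T * B)
  dA1[cc$A1 <= 0] <- 0
  dW1 <- tcrossprod(dA1, cc$Xmat)
  db1 <- rowSums(dA1)

  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1,
                    W2 = array(dW2mat, dim = dim(params$W2)), b2 = db2,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4))
}

#' Training configuration for the networks
#'
#' Mini-batch training with an adaptive learning-rate schedule: when the
#' validation error rate stops improving for `patience` consecutive epochs at
#' the current learning rate, the rate is divided by `lr_divisor`; training
#' terminates after `max_lr_drops` reductions (or at `max_epochs`). The
#' parameters with the best validation error are returned.
#'
#' @param batch_size Mini-batch size.
#' @param alpha0 Initial learning rate.
#' @param lr_divisor Factor the learning rate is divided by on a plateau.
#' @param max_lr_drops Number of reductions before termination.
#' @param patience Epochs without a new validation minimum that define a
#'   plateau.
#' @param val_fraction Fraction of training trials held out for validation.
#' @param max_epochs Hard cap on epochs.
#' @param lambda L2 weight-decay strength (used by the MLP loss).
#' @param standardize Standardize inputs with training-split statistics.
#' @param seed Seed controlling the validation split and batch order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 128, alpha0 = 1e-4, lr_divisor = 3,
                         max_lr_drops = 3, patience = 5, val_fraction = 0.1,
                         max_epochs = 40, lambda = 1e-3, standardize = TRUE,
                         seed = 1L) {
  stopifnot(batch_size >= 1, alpha0 > 0)
  structure(list(batch_size = as.integer(batch_size), alpha0 = alpha0,
                 lr_divisor = lr_divisor, max_lr_drops = max_lr_drops,
                 patience = patience, val_fraction = val_fraction,
                 max_epochs = max_epochs, lambda = lambda,
                 standardize = standardize, seed = as.integer(seed)),
            class = "train_config")
}

# Shared training loop for the two networks; `loss_grad(params, batch_idx)`
# and `val_error(params)` close over the data. If every rectifier path
# below the output dies (the first-layer gradient is exactly zero for a
# full epoch), the network can never recover, so it is re-initialized from
# the current RNG stream (a deterministic random restart).
run_training <- function(params, opt_state, step_fun, loss_grad, val_error,
                         n_train, cfg, reinit = NULL) {
  history <- list()
  best <- list(err = Inf, params = params, epoch = 0L)
  drops <- 0L
  since_best <- 0L
  epoch <- 0L
  restarts <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    g1_norm <- 0
    for (bi in batches) {
      lg <- loss_grad(params, bi)
      ep_loss <- ep_loss + lg$loss * length(bi)
      g1_norm <- g1_norm + sum(abs(lg$grads[[1]]))
      upd <- step_fun(params, lg$grads, opt_state)
      params <- upd$params
      opt_state <- upd$state
    }
    if (g1_norm == 0 && !is.null(reinit) && restarts < 3L) {
      restarts <- restarts + 1L
      fresh <- reinit()
      params <- fresh$params
      opt_state <- fresh$state
    }
    err <- val_error(params)
    history[[epoch]] <- c(epoch = epoch, loss = ep_loss / n_train,
                          val_error = err, lr = opt_state$alpha)
    if (err < best$err - 1e-12) {
      best <- list(err = err, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= cfg$patience) {
      if (drops >= cfg$max_lr_drops) break
      opt_state$alpha <- opt_state$alpha / cfg$lr_divisor
      drops <- drops + 1L
      since_best <- 0L
    }
    if (epoch >= cfg$max_epochs) break
  }
  hist <- tibble::as_tibble(do.call(rbind, history))
  list(params = best$params, best_val_error = best$err, history = hist,
       final_params = params, restarts = restarts)
}

# Stratified validation split: a seeded shuffle, then the final fraction.
val_split <- function(labels, fraction) {
  n <- length(labels)
  ord <- sample.int(n)
  n_val <- max(1L, round(n * fraction))
  list(train = ord[seq_len(n - n_val)], val = ord[(n - n_val + 1L):n])
}

#' Train the CNN decoder
#'
#' Mini-batch Adam on the cross-entropy loss with the plateau-based
#' learning-rate schedule of [train_config()]. A validation split is carved
#' from the training trials by seed; the parameters achieving the best
#' validation error are returned.
#'
#' @param train An [epoch_set()] with both classes present.
#' @param cfg A [train_config()].
#' @param spec Optional [cnn_spec()]; defaults to the epoch dimensions.
#' @return An object of class `cnn_fit`: parameters, spec, training history
#'   (one row per epoch: loss, validation error, learning rate), scaling
#'   statistics if standardization is on, and the configuration.
#' @export
train_cnn <- function(train, cfg = train_config(), spec = NULL) {
  stopifnot(inherits(train, "epoch_set"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  d <- dim(train$data)
  spec <- spec %||% cnn_spec(n_channels = d[2], n_samples = d[3])
  # channel x (time*trial) layout built once; standardization acts on rows
  Xall <- batch_to_mat(train$data)
  scaling <- NULL
  if (isTRUE(cfg$standardize)) {
    mu <- rowMeans(Xall)
    sd <- sqrt(rowMeans((Xall - mu)^2))
    sd[sd == 0] <- 1
    Xall <- (Xall - mu) / sd
    scaling <- list(mean = mu, sd = sd)
  }
  res <- with_seed(cfg$seed, {
    sp <- val_split(train$labels, cfg$val_fraction)
    yt <- train$labels[sp$train]
    yv <- train$labels[sp$val]
    cols_of <- function(idx) {
      as.vector(outer(seq_len(spec$T), (idx - 1L) * spec$T, `+`))
    }
    Xt <- cnn_data_ptr(Xall[, cols_of(sp$train), drop = FALSE])
    Xv <- cnn_data_ptr(Xall[, cols_of(sp$val), drop = FALSE])
    pass <- function(p, ptr, idx, y, backward) {
      cnn_pass_train(ptr, as.integer(idx), p$W1, p$b1,
                     matrix(p$W2, spec$K2, spec$K1 * spec$klen),
                     p$b2, p$W3, p$b3, p$W4, p$b4, spec$T, spec$pool,
                     spec$klen, spec$padl, as.integer(y), backward)
    }
    params <- init_cnn(spec, seed = sample.int(.Machine$integer.max, 1))
    state <- adam_state(params, alpha = cfg$alpha0)
    reinit <- function() {
      p <- init_cnn(spec, seed = sample.int(.Machine$integer.max, 1))
      list(params = p, state = adam_state(p, alpha = cfg$alpha0))
    }
    run_training(
      params, state, adam_step,
      loss_grad = function(p, idx) {
        r <- pass(p, Xt, idx, yt[idx], TRUE)
        list(loss = r$loss,
             grads = list(W1 = r$dW1, b1 = drop(r$db1),
                          W2 = array(r$dW2, dim = dim(p$W2)),
                          b2 = drop(r$db2), W3 = r$dW3, b3 = drop(r$db3),
                          W4 = r$dW4, b4 = drop(r$db4)))
      },
      val_error = function(p) {
        r <- pass(p, Xv, seq_along(yv), yv, FALSE)
        mean((max.col(r$probs) - 1L) != yv)
      },
      n_train = length(yt), cfg = cfg, reinit = reinit
    )
  })
  structure(list(params = res$params, spec = spec, history = res$history,
                 best_val_error = res$best_val_error, scaling = scaling,
                 restarts = res$restarts, config = cfg,
                 class_names = train$class_names),
            class = "cnn_fit")
}

#' @export
predict.cnn_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "epoch_set")) {
    if (!is.null(object$scaling)) {
      newdata <- standardize(newdata, stats = object$scaling)
    }
    newdata <- newdata$data
  }
  pr <- cnn_forward(object$params, newdata, object$spec)
  colnames(pr) <- object$class_names
  if (type == "prob") pr else max.col(pr) - 1L
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat("<cnn_fit> ", x$spec$C, "x", x$spec$T, " input, ",
      nrow(x$history), " epochs, best validation error ",
      signif(x$best_val_error, 3), "\n", sep = "")
  invisible(x)
}

#' Per-channel importance from the spatial layer
#'
#' The spatial kernels of the first layer have no time extent, so averaging
#' their weights along the timepoints reduces to averaging the absolute
#' weight each channel receives across the kernels. Scores are non-negative,
#' one per input channel.
#'
#' @param fit A `cnn_fit`, or a raw parameter list.
#' @return Numeric vector of length `C`.
#' @export
cnn_channel_importance <- function(fit) {
  W1 <- if (inherits(fit, "cnn_fit")) fit$params$W1 else fit$W1
  colMeans(abs(W1))
}
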