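#' Decoder pipeline specification
#'
#' Bundles one of the three decoding pipelines with its configuration so
#' cross-validation can fit and apply it inside each training fold:
#'
#' * `"cnn"` — optional per-channel standardization (training-split
#'   statistics), crop to the 2-s post-cue window, then the raw-signal
#'   convolutional network trained with Adam.
#' * `"mlp"` — small-Laplacian spatial filter, crop, standardization, then
#'   the 1000/300/80 perceptron trained with RMSprop and weight decay.
#' * `"csp-svm"` — CSP projection, sliding multitaper log-PSD features,
#'   canonical discriminant ranking with a fixed or grid-searched feature
#'   count, a linear SVM with Platt probabilities, and evidence
#'   accumulation to a trial decision.
#' * `"custom"` — user-supplied `fit(train, seed)` / `predict(fit, test)`
#'   closures, mainly for testing the evaluation machinery.
#'
#' @param model One of `"cnn"`, `"mlp"`, `"csp-svm"`, `"custom"`.
#' @param ... Configuration overrides. For the networks these are
#'   [train_config()] arguments plus `epoch_window`; for `"csp-svm"`:
#'   `n_pairs` (CSP filter pairs), `use_csp`, `n_features`, `grid` (feature-count
#'   grid searched on an inner validation split when supplied), `cost`,
#'   `alpha_s`, `threshold`, and [multitaper_psd()] parameters.
#' @return An object of class `decoder_spec`.
#' @export
decoder_pipeline <- function(model = c("cnn", "mlp", "csp-svm", "custom"),
                             ...) {
  model <- match.arg(model)
  config <- list(...)
  defaults <- switch(model,
    "cnn" = list(epoch_window = c(0, 2), standardize = TRUE),
    "mlp" = list(epoch_window = c(0, 2), standardize = TRUE, lambda = 1e-3),
    "csp-svm" = list(n_pairs = 3, use_csp = TRUE, n_features = 60, grid = NULL,
                     cost = 1, alpha_s = 0.95, threshold = 0.75,
                     win = 1, step = 0.0625, fmin = 4, fmax = 48,
                     bin_width = 2, nw = 2, k_tapers = 3),
    "custom" = list()
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  structure(list(model = model, config = config), class = "decoder_spec")
}

# Crop epochs to a time window (seconds, half-open) when they are longer.
crop_epochs <- function(x, window) {
  d <- dim(x$data)
  s0 <- floor(window[1] * x$fs) + 1L
  s1 <- min(floor(window[2] * x$fs), d[3])
  if (s0 == 1L && s1 == d[3]) return(x)
  epoch_set(x$data[, , s0:s1, drop = FALSE], x$labels, x$fs, x$montage,
            x$class_names)
}

net_config <- function(config, seed) {
  args <- config[intersect(names(config), names(formals(train_config)))]
  args$seed <- seed
  do.call(train_config, args)
}

#' Fit a decoder pipeline on training epochs
#'
#' @param spec A [decoder_pipeline()].
#' @param train Training [epoch_set()].
#' @param seed Seed for all randomness in the fit.
#' @return An object of class `decoder_fit`.
#' @export
fit_decoder <- function(spec, train, seed = 1L) {
  cfg <- spec$config
  fit <- switch(spec$model,
    "cnn" = {
      tr <- crop_epochs(train, cfg$epoch_window)
      train_cnn(tr, net_config(cfg, seed))
    },
    "mlp" = {
      tr <- crop_epochs(small_laplacian(train), cfg$epoch_window)
      train_mlp(tr, net_config(cfg, seed))
    },
    "csp-svm" = fit_csp_svm(cfg, train, seed),
    "custom" = cfg$fit(train, seed)
  )
  structure(list(model = spec$model, spec = spec, fit = fit),
            class = "decoder_fit")
}

fit_csp_svm <- function(cfg, train, seed) {
  csp <- if (isTRUE(cfg$use_csp)) fit_csp(train, m = cfg$n_pairs) else NULL
  proj <- if (is.null(csp)) train else apply_csp(csp, train)
  feats <- multitaper_psd(proj, win = cfg$win, step = cfg$step,
                          fmin = cfg$fmin, fmax = cfg$fmax,
                          bin_width = cfg$bin_width, nw = cfg$nw,
                          k = cfg$k_tapers)
  rl <- row_labels(feats, train$labels)
  X <- feature_matrix(feats)
  curve <- NULL
  if (!is.null(cfg$grid)) {
    # inner stratified trial split for the feature-count search
    inner <- with_seed(seed, val_split(train$labels, 0.2))
    r_tr <- feats$trial %in% inner$train
    sel_res <- select_feature_count(
      X[r_tr, , drop = FALSE], rl[r_tr],
      X[!r_tr, , drop = FALSE], rl[!r_tr],
      grid = cfg$grid, cost = cfg$cost
    )
    n_features <- sel_res$best
    curve <- sel_res$curve
  } else {
    n_features <- min(cfg$n_features, ncol(X))
  }
  ranking <- cva_rank(feats, rl)
  sel <- order(ranking$rank)[seq_len(n_features)]
  svm <- train_svm(X[, sel, drop = FALSE], rl, cost = cfg$cost)
  list(csp = csp, ranking = ranking, selected = sel,
       n_features = n_features, selection_curve = curve, svm = svm,
       state = evidence_state(cfg$alpha_s, cfg$threshold),
       config = cfg)
}

#' Predict trial labels with a fitted decoder
#'
#' @param object A `decoder_fit`.
#' @param newdata Test [epoch_set()].
#' @param details For the CSP-SVM pipeline, also return window-level
#'   predictions, crossing times and timeout flags.
#' @param ... Unused.
#' @return Integer vector of 0/1 trial decisions, or a list when
#'   `details = TRUE`.
#' @export
predict.decoder_fit <- function(object, newdata, details = FALSE, ...) {
  cfg <- object$spec$config
  if (object$model %in% c("cnn", "mlp")) {
    te <- if (object$model == "mlp") small_laplacian(newdata) else newdata
    te <- crop_epochs(te, cfg$epoch_window)
    return(predict(object$fit, te, type = "class"))
  }
  if (object$model == "custom") {
    return(cfg$predict(object$fit, newdata))
  }
  f <- object$fit
  proj <- if (is.null(f$csp)) newdata else apply_csp(f$csp, newdata)
  feats <- multitaper_psd(proj, win = cfg$win, step = cfg$step,
                          fmin = cfg$fmin, fmax = cfg$fmax,
                          bin_width = cfg$bin_width, nw = cfg$nw,
                          k = cfg$k_tapers)
  X <- feature_matrix(feats)[, f$selected, drop = FALSE]
  p <- svm_probability(f$svm, X)
  trials <- sort(unique(feats$trial))
  dec <- integer(length(trials))
  crossed <- integer(length(trials))
  timeout <- logical(length(trials))
  for (i in seq_along(trials)) {
    rows <- which(feats$trial == trials[i])
    rows <- rows[order(feats$window[rows])]
    ev <- accumulate_evidence(p[rows], f$state)
    dec[i] <- ev$decision
    crossed[i] <- ev$crossed_at %||% NA_integer_
    timeout[i] <- ev$timeout
  }
  if (!details) return(dec)
  list(decision = dec, crossed_at = crossed, timeout = timeout,
       window_class = as.integer(p > 0.5), window_prob = p,
       window_trial = feats$trial)
}
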