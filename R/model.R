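# Public model API: architecture/training/augmentation configuration,
# model construction and training, prediction and embedding extraction.

#' Architecture configuration for the stroke classifier
#'
#' The default `cnn_bilstm` variant is a two-stage convolutional block
#' followed by a bidirectional LSTM: a temporal convolution with (5 x 1)
#' kernels learns intra-channel dynamics, batch normalization + ReLU +
#' (2 x 1) max pooling halve the time axis, then a (1 x 12) "spatial fusion"
#' convolution cross-correlates all 12 bilateral channels at each time step,
#' collapsing the channel axis to one and yielding a 50-step sequence that a
#' 128-unit bidirectional LSTM reads in both directions; the concatenated
#' final hidden states pass through dropout into a softmax output.
#' Ablation variants drop the recurrent block (`cnn_only`, global average
#' pooling instead) or the convolutional blocks (`bilstm_only`, `gru_only`,
#' operating on the raw 100 x 12 sequence).
#'
#' @param variant One of `"cnn_bilstm"`, `"cnn_only"`, `"bilstm_only"`,
#'   `"gru_only"`.
#' @param temporal_kernel Temporal kernel length (default 5).
#' @param temporal_filters,spatial_filters Filter counts (defaults 32, 64).
#' @param bilstm_units Recurrent units per direction (default 128).
#' @param dropout Dropout rate on the penultimate representation
#'   (default 0.5, must be in \[0, 1)).
#' @param n_classes Output classes (default 2).
#' @param n_channels Input sensor channels (12: both wrists x 6 axes).
#' @return A list of class `architecture_config`.
#' @export
architecture_config <- function(variant = c("cnn_bilstm", "cnn_only",
                                            "bilstm_only", "gru_only"),
                                temporal_kernel = 5L, temporal_filters = 32L,
                                spatial_filters = 64L, bilstm_units = 128L,
                                dropout = 0.5, n_classes = 2L,
                                n_channels = 12L) {
  variant <- match.arg(variant)
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must be in [0, 1).", class = "strokesense_value_error")
  }
  structure(
    list(variant = variant, temporal_kernel = as.integer(temporal_kernel),
         temporal_filters = as.integer(temporal_filters),
         spatial_filters = as.integer(spatial_filters),
         bilstm_units = as.integer(bilstm_units), dropout = dropout,
         n_classes = as.integer(n_classes),
         n_channels = as.integer(n_channels)),
    class = "architecture_config"
  )
}

#' Training configuration
#'
#' Defaults: Adam at learning rate 1e-3 with step decay (gamma 0.2 every 15
#' epochs), decoupled weight decay 5e-3 on weight matrices, cross-entropy
#' loss, batch size 64, 50 epochs.
#'
#' @param lr Initial learning rate.
#' @param gamma,step_size Step-decay factor and interval (epochs).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, gamma = 0.2, step_size = 15L,
                         weight_decay = 5e-3, batch_size = 64L, epochs = 50L,
                         seed = 1L) {
  vals <- c(lr, gamma, step_size, weight_decay, batch_size, epochs)
  if (any(vals <= 0)) {
    abort("All training-config values must be positive.",
          class = "strokesense_value_error")
  }
  structure(
    list(lr = lr, gamma = gamma, step_size = as.integer(step_size),
         weight_decay = weight_decay, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate in force at a given epoch
#'
#' Step decay: `lr * gamma^floor((epoch - 1) / step_size)`, e.g. 1e-3 for
#' epochs 1-15, 2e-4 for 16-30, 4e-5 for 31-45 with the defaults.
#'
#' @param config A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$gamma^((epoch - 1L) %/% config$step_size)
}

#' Augmentation configuration
#'
#' Random time shifting (edge replication), low-intensity Gaussian jitter
#' scaled to each channel's RMS, and amplitude scaling.
#'
#' @param shift_max Maximum absolute shift in samples (default 5; must stay
#'   below the 40-sample pre-impact phase).
#' @param jitter_sd_fraction Jitter SD as a fraction of per-channel RMS
#'   (default 0.02).
#' @param scale_range Amplitude scale range (default \[0.9, 1.1\]).
#' @param copies_per_window Augmented copies per training window (default 1,
#'   nearly doubling the training set).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(shift_max = 5L, jitter_sd_fraction = 0.02,
                           scale_range = c(0.9, 1.1),
                           copies_per_window = 1L) {
  if (shift_max >= 40L) {
    abort("shift_max must be below the 40-sample pre-impact span.",
          class = "strokesense_value_error")
  }
  if (any(scale_range <= 0) || any(scale_range >= 2)) {
    abort("scale_range must lie within (0, 2).",
          class = "strokesense_value_error")
  }
  structure(
    list(shift_max = as.integer(shift_max),
         jitter_sd_fraction = jitter_sd_fraction,
         scale_range = scale_range,
         copies_per_window = as.integer(copies_per_window)),
    class = "augment_config"
  )
}

#' Augment training windows (held-out windows untouched)
#'
#' Each training window gains `copies_per_window` augmented variants (random
#' time shift with edge replication, per-channel RMS-scaled Gaussian jitter,
#' and a single amplitude factor); windows outside `train_mask` pass through
#' bit-identical, so evaluation always sees unaltered signals. Uses the
#' current RNG state.
#'
#' @param tensor A [window_tensor].
#' @param train_mask Logical vector (length N) flagging training windows.
#' @param config An [augment_config()].
#' @return A `window_tensor` whose `meta` gains `augmented` (logical) and
#'   `source_row` (originating window); originals come first in original
#'   order, augmented copies after.
#' @export
augment <- function(tensor, train_mask, config = augment_config()) {
  stopifnot(inherits(tensor, "window_tensor"))
  n <- dim(tensor$windows)[1]
  if (length(train_mask) != n || !any(train_mask)) {
    abort("train_mask must cover all windows and be non-empty.",
          class = "strokesense_value_error")
  }
  src <- rep(which(train_mask), each = config$copies_per_window)
  aug_windows <- vector("list", length(src))
  for (j in seq_along(src)) {
    w <- tensor_window(tensor, src[j])
    s <- sample.int(2L * config$shift_max + 1L, 1L) - config$shift_max - 1L
    idx <- pmin(pmax(1:100 + s, 1L), 100L)   # edge replication
    out <- w[idx, , drop = FALSE]
    rms <- sqrt(colMeans(w^2))
    out <- out + matrix(rnorm(1200L), 100L, 12L) *
      rep(config$jitter_sd_fraction * rms, each = 100L)
    aug_windows[[j]] <- out * runif(1L, config$scale_range[1],
                                    config$scale_range[2])
  }
  orig_meta <- dplyr::mutate(tensor$meta, augmented = FALSE,
                             source_row = seq_len(n))
  aug_meta <- dplyr::mutate(tensor$meta[src, ], augmented = TRUE,
                            source_row = src)
  all_windows <- c(lapply(seq_len(n), tensor_window, tensor = tensor),
                   aug_windows)
  assemble_tensor(all_windows, dplyr::bind_rows(orig_meta, aug_meta))
}

#' Build an untrained stroke classifier
#'
#' Initializes parameters (He-scaled convolutions, uniform recurrent
#' weights with a +1 forget-gate bias) for the requested variant, using the
#' current RNG state.
#'
#' @param arch An [architecture_config()].
#' @return An object of class `stroke_model` (untrained).
#' @export
build_model <- function(arch = architecture_config()) {
  params <- init_params(arch, arch$n_channels)
  structure(
    list(arch = arch, params = params, bn_state = init_bn_state(arch),
         scaler = NULL, classes = NULL,
         history = tibble::tibble(epoch = integer(), loss = numeric(),
                                  lr = numeric(), val_accuracy = numeric()),
         trained = FALSE),
    class = "stroke_model"
  )
}

#' @noRd
tensor_to_array <- function(x) {
  if (inherits(x, "window_tensor")) x <- x$windows
  d <- dim(x)
  if (length(d) == 4L) x <- array(x, d[1:3])
  x
}

# Per-channel standardization fitted on training data only; stored in the
# model and re-applied at prediction time.
#' @noRd
fit_channel_scaler <- function(x) {
  ch_mean <- apply(x, 3L, mean)
  ch_sd <- apply(x, 3L, sd)
  ch_sd[ch_sd == 0] <- 1
  list(mean = ch_mean, sd = ch_sd)
}

#' @noRd
apply_channel_scaler <- function(x, scaler) {
  for (c_ in seq_len(dim(x)[3])) {
    x[, , c_] <- (x[, , c_] - scaler$mean[c_]) / scaler$sd[c_]
  }
  x
}

#' Train the stroke classifier
#'
#' Mini-batch Adam with step-decayed learning rate, decoupled weight decay
#' and cross-entropy loss. Inputs are standardized per channel with
#' statistics fitted on the training data only (stored in the model).
#' Training is deterministic for a fixed seed on a given platform.
#'
#' @param model A [build_model()] result, or an [architecture_config()] (a
#'   fresh model is initialized from it under the training seed).
#' @param tensor A [window_tensor] or N x 100 x 12 (x 1) array.
#' @param labels Class label vector of length N (>= 2 classes present).
#' @param config A [train_config()].
#' @param val_tensor,val_labels Optional held-out data; per-epoch accuracy on
#'   it is recorded in the history.
#' @return A trained `stroke_model` with a per-epoch `history` tibble
#'   (`epoch`, `loss`, `lr`, `val_accuracy`).
#' @export
train_model <- function(model, tensor, labels, config = train_config(),
                        val_tensor = NULL, val_labels = NULL) {
  x <- tensor_to_array(tensor)
  y_fac <- factor(labels)
  if (nlevels(y_fac) < 2L) {
    abort("Training data must contain at least 2 classes.",
          class = "strokesense_value_error")
  }
  n <- dim(x)[1]
  if (config$batch_size > n) {
    abort("Batch size exceeds the number of training windows.",
          class = "strokesense_value_error")
  }
  set.seed(config$seed)
  if (inherits(model, "architecture_config")) model <- build_model(model)
  stopifnot(inherits(model, "stroke_model"))
  arch <- model$arch
  y <- as.integer(y_fac)
  model$classes <- levels(y_fac)
  model$scaler <- fit_channel_scaler(x)
  x <- apply_channel_scaler(x, model$scaler)
  xv <- if (!is.null(val_tensor)) {
    apply_channel_scaler(tensor_to_array(val_tensor), model$scaler)
  }
  params <- model$params
  bn_state <- model$bn_state
  opt <- list(t = 0L,
              m = lapply(params, function(p) p * 0),
              v = lapply(params, function(p) p * 0))
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      if (length(take) < 2L) next   # BN needs at least 2 rows
      xb <- x[take, , , drop = FALSE]
      fwd <- net_forward(params, xb, arch, bn_state, train = TRUE)
      bn_state <- fwd$bn_state
      ce <- softmax_ce(fwd$logits, y[take])
      grads <- net_backward(params, ce$dlogits, arch, fwd$cache)
      upd <- adam_update(params, grads, opt, lr, config$weight_decay)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + ce$loss; n_batches <- n_batches + 1L
    }
    val_acc <- NA_real_
    if (!is.null(xv)) {
      fwd <- net_forward(params, xv, arch, bn_state, train = FALSE)
      pred <- model$classes[max.col(fwd$logits, ties.method = "first")]
      val_acc <- mean(pred == as.character(val_labels))
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = ep_loss / n_batches,
                                       lr = lr, val_accuracy = val_acc)
  }
  model$params <- params
  model$bn_state <- bn_state
  model$history <- dplyr::bind_rows(history)
  model$train_config <- config
  model$trained <- TRUE
  model
}

#' @export
print.stroke_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<stroke_model> %s, %d parameters, %s\n", x$arch$variant, np,
              if (x$trained) sprintf("trained %d epochs (final loss %.4f)",
                                     nrow(x$history),
                                     x$history$loss[nrow(x$history)])
              else "untrained"))
  invisible(x)
}

#' Predict expertise classes and probabilities
#'
#' @param object A trained `stroke_model`.
#' @param tensor A [window_tensor] or array of windows.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and one `.prob_<class>` column per
#'   class (rows sum to 1). Zero windows give a zero-row tibble.
#' @export
predict.stroke_model <- function(object, tensor, ...) {
  if (!object$trained) {
    abort("Model is not trained.", class = "strokesense_value_error")
  }
  x <- tensor_to_array(tensor)
  out_cols <- c(".pred_class", paste0(".prob_", object$classes))
  if (dim(x)[1] == 0L) {
    out <- tibble::as_tibble(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(object$classes))),
      out_cols))
    return(out)
  }
  x <- apply_channel_scaler(x, object$scaler)
  fwd <- net_forward(object$params, x, object$arch, object$bn_state,
                     train = FALSE)
  sm <- softmax_ce(fwd$logits, rep(1L, nrow(fwd$logits)))
  probs <- sm$probs
  cls <- object$classes[max.col(probs, ties.method = "first")]
  out <- tibble::as_tibble(setNames(
    c(list(cls), lapply(seq_along(object$classes), function(j) probs[, j])),
    out_cols))
  out
}

#' Penultimate-layer embeddings
#'
#' Returns the learned representation entering the output layer (the
#' concatenated final hidden states of both recurrent directions, 256-dim
#' for the default configuration), e.g. as input for an external t-SNE
#' projection.
#'
#' @param model A trained `stroke_model`.
#' @param tensor A [window_tensor] or array of windows.
#' @return An N x D numeric matrix; deterministic for fixed weights.
#' @export
embed <- function(model, tensor) {
  if (!model$trained) {
    abort("Model is not trained.", class = "strokesense_value_error")
  }
  x <- apply_channel_scaler(tensor_to_array(tensor), model$scaler)
  net_forward(model$params, x, model$arch, model$bn_state, train = FALSE)$emb
}

#' @export
tidy.stroke_model <- function(x, ...) x$history

#' @export
glance.stroke_model <- function(x, ...) {
  tibble::tibble(
    variant = x$arch$variant,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_
  )
}
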