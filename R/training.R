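# Data splitting, loss functions, optimizers, and the training loops.

#' Stratified train/validation/test assignment of labels
#'
#' Assigns each item to train/val/test within its class, using
#' largest-remainder rounding so per-class counts are exact proportions of
#' the class size (a 6000-item class at 0.8/0.1/0.1 gives 4800/600/600).
#'
#' @param labels Integer (or factor) class labels, one per item.
#' @param fractions Numeric of length 3 (train, val, test); positive, sums
#'   to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return Character vector of `"train"`/`"val"`/`"test"` tags.
#' @export
split_indices <- function(labels, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 0L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 3 positive proportions summing to 1", call. = FALSE)
  }
  labels <- as.integer(factor(labels))
  tags <- character(length(labels))
  with_seed(seed, {
    for (ci in unique(labels)) {
      idx <- which(labels == ci)
      n <- length(idx)
      if (n < 10L) {
        warning(sprintf("class %d has only %d items; proportional rounding applied",
                        ci, n), call. = FALSE)
      }
      exact <- n * fractions
      base <- floor(exact)
      rem <- exact - base
      short <- n - sum(base)
      if (short > 0) {              # largest remainders absorb the leftover
        add <- order(rem, decreasing = TRUE)[seq_len(short)]
        base[add] <- base[add] + 1
      }
      idx <- sample(idx)
      tags[idx] <- rep(c("train", "val", "test"), times = base)
    }
  })
  tags
}

#' Split a patch set into train/validation/test
#'
#' Stratified by class via [split_indices()]; the split is a partition and is
#' reproducible for a fixed seed.
#'
#' @param set A [patch_set()].
#' @param fractions Train/val/test proportions (positive, sum to 1).
#' @param seed Integer seed.
#' @return The patch set with `split` tags filled in.
#' @export
split_patchset <- function(set, fractions = c(train = 0.8, val = 0.1, test = 0.1),
                           seed = 0L) {
  stopifnot(inherits(set, "patch_set"))
  set$split <- split_indices(set$labels, fractions, seed)
  set
}

#' Cross-entropy losses
#'
#' `binary_ce(p, t)` is the binary cross entropy
#' `-t log p - (1 - t) log(1 - p)` with `p` the predicted probability of
#' label 1 and `t` in `{0, 1}`. `categorical_ce(y, t)` is
#' `-sum_i t_i log y_i` for a normalized probability vector `y` and a one-hot
#' target `t`. Both use natural logarithms and clip probabilities at 1e-7
#' before the log for numerical safety. Vectorized: `p`/`t` may be vectors,
#' `y`/`t` may be matrices with one row per item.
#'
#' @param p Predicted probability (or vector) of label 1.
#' @param t Binary label(s) in `{0, 1}`, or a one-hot matrix/vector for
#'   `categorical_ce`.
#' @param y Probability matrix (rows sum to 1) or single vector.
#' @return Loss value(s), natural-log units.
#' @export
binary_ce <- function(p, t) {
  if (!all(t %in% c(0, 1))) stop("`t` must be 0/1", call. = FALSE)
  p <- clamp(p, 1e-7, 1 - 1e-7)
  -t * log(p) - (1 - t) * log(1 - p)
}

#' @rdname binary_ce
#' @export
categorical_ce <- function(y, t) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (is.vector(t)) t <- matrix(t, nrow = 1)
  if (any(abs(rowSums(y) - 1) > 1e-6)) {
    stop("rows of `y` must be normalized probabilities", call. = FALSE)
  }
  if (!all(t %in% c(0, 1)) || any(rowSums(t) != 1)) {
    stop("`t` must be one-hot", call. = FALSE)
  }
  y <- clamp(y, 1e-7, 1)
  as.vector(-rowSums(t * log(y)))
}

#' Training configuration
#'
#' Defaults follow the training protocol used throughout: Adam with learning
#' rate 0.001, beta1 0.9, beta2 0.999, batch size 64, 50 epochs, seed 1337.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Positive step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam denominator offset.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of epochs (>= 1).
#' @param seed Integer seed controlling initialization order, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         momentum = 0, batch_size = 64L, epochs = 50L,
                         seed = 1337L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# One optimizer step over the trainable layers of `net`.
# `state` holds Adam moments / SGD velocity per layer; `t` is the Adam step.
optim_step <- function(net, grads, config, state, t) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    if (!isTRUE(ly$trainable)) next
    if (config$optimizer == "adam") {
      st <- state[[i]] %||% list(mW = 0 * ly$W, vW = 0 * ly$W,
                                 mb = 0 * ly$b, vb = 0 * ly$b)
      st$mW <- config$beta1 * st$mW + (1 - config$beta1) * g$dW
      st$vW <- config$beta2 * st$vW + (1 - config$beta2) * g$dW^2
      st$mb <- config$beta1 * st$mb + (1 - config$beta1) * g$db
      st$vb <- config$beta2 * st$vb + (1 - config$beta2) * g$db^2
      mhat <- st$mW / (1 - config$beta1^t)
      vhat <- st$vW / (1 - config$beta2^t)
      ly$W <- ly$W - config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
      mbh <- st$mb / (1 - config$beta1^t)
      vbh <- st$vb / (1 - config$beta2^t)
      ly$b <- ly$b - config$learning_rate * mbh / (sqrt(vbh) + config$epsilon)
      state[[i]] <- st
    } else {
      st <- state[[i]] %||% list(vW = 0 * ly$W, vb = 0 * ly$b)
      st$vW <- config$momentum * st$vW - config$learning_rate * g$dW
      st$vb <- config$momentum * st$vb - config$learning_rate * g$db
      ly$W <- ly$W + st$vW
      ly$b <- ly$b + st$vb
      state[[i]] <- st
    }
    net$layers[[i]] <- ly
  }
  list(net = net, state = state)
}

# Slice a batch from conv-domain (4-d) or dense-domain (matrix) inputs.
batch_slice <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[, , , idx, drop = FALSE]
}

onehot <- function(labels, k) {
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

# Mini-batch training of one net on (x, labels). Returns the best-epoch
# snapshot (highest validation accuracy, earliest epoch on ties) plus the
# per-epoch history.
fit_net <- function(net, x_train, y_train, x_val, y_val, config) {
  k <- utils::tail(net$layers, 1)[[1]]$output_shape
  n <- length(y_train)
  state <- vector("list", length(net$layers))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, net = net)
  t_step <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      losses <- numeric()
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- batch_slice(x_train, idx)
        tb <- onehot(y_train[idx], k)
        fw <- net_forward(net, xb, train = TRUE, cache = TRUE)
        probs <- clamp(fw$out, 1e-7, 1)
        losses <- c(losses, mean(-rowSums(tb * log(probs))))
        dtop <- (fw$out - tb) / length(idx)
        grads <- net_backward(net, fw$caches, dtop)
        t_step <- t_step + 1L
        upd <- optim_step(net, grads, config, state, t_step)
        net <- upd$net; state <- upd$state
      }
      val <- predict_in_chunks(net, x_val)
      val_probs <- clamp(val, 1e-7, 1)
      val_loss <- mean(-rowSums(onehot(y_val, k) * log(val_probs)))
      val_acc <- mean(max.col(val, ties.method = "first") == y_val)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = mean(losses),
        val_loss = val_loss, val_acc = val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, epoch = ep, net = net)
      }
    }
  })
  list(net = best$net, history = history, best_epoch = best$epoch)
}

predict_in_chunks <- function(net, x, chunk = 64L) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[4]
  k <- utils::tail(net$layers, 1)[[1]]$output_shape
  out <- matrix(0, n, k)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    out[idx, ] <- net_forward(net, batch_slice(x, idx), train = FALSE)
  }
  out
}

#' Train a classifier on a tagged patch set
#'
#' Mini-batch training with the configured optimizer and seeded shuffling.
#' After every epoch the model is evaluated on the validation split; the
#' epoch with the highest validation accuracy (earliest on ties) is retained
#' as the returned snapshot. When the classifier has a frozen extractor, the
#' features of the train and validation splits are computed once and only
#' the dense head is trained — the transfer-learning fast path. When
#' `extractor` is `NULL` the head net (a full CNN) trains end to end on the
#' preprocessed pixels.
#'
#' @param classifier An [acne_classifier()] with initialized weights.
#' @param data A [patch_set()] with train and val split tags.
#' @param config A [train_config()].
#' @return List with `classifier` (best-epoch snapshot), `history`
#'   (per-epoch train loss, validation loss and accuracy), and `best_epoch`.
#' @export
train_classifier <- function(classifier, data, config = train_config()) {
  stopifnot(inherits(classifier, "acne_classifier"),
            inherits(data, "patch_set"), inherits(config, "train_config"))
  if (is.null(data$split)) stop("`data` must carry split tags", call. = FALSE)
  tr <- split_patches(data, "train")
  va <- split_patches(data, "val")
  if (n_patches(tr) == 0L || n_patches(va) == 0L) {
    stop("train and val splits must be non-empty", call. = FALSE)
  }
  if (!is.null(classifier$extractor)) {
    x_train <- extract_features(classifier$extractor, tr, classifier$preproc)
    x_val <- extract_features(classifier$extractor, va, classifier$preproc)
  } else {
    x_train <- preprocess(tr$x, classifier$preproc)
    x_val <- preprocess(va$x, classifier$preproc)
  }
  fit <- fit_net(classifier$head, x_train, tr$labels, x_val, va$labels, config)
  classifier$head <- fit$net
  list(classifier = classifier, history = fit$history,
       best_epoch = fit$best_epoch)
}

#' Calibrate the binary decision threshold on the validation split
#'
#' Sets the classifier's decision threshold to the Youden-index optimum of
#' the validation ROC (the "best threshold" of the threshold report).
#'
#' @param classifier A trained binary [acne_classifier()].
#' @param data A tagged [patch_set()] with a val split.
#' @param positive_class Name of the positive class (default the first).
#' @return The classifier with `threshold` set.
#' @export
calibrate_threshold <- function(classifier, data,
                                positive_class = classifier$class_names[1]) {
  va <- split_patches(data, "val")
  probs <- predict(classifier, va)
  scores <- probs[, positive_class]
  truth <- as.integer(va$labels == match(positive_class, classifier$class_names))
  yb <- youden_best(roc_curve(scores, truth))
  thr <- yb$best_threshold
  if (!is.finite(thr)) thr <- 0.5
  classifier$threshold <- clamp(thr, 1e-6, 1 - 1e-6)
  classifier
}

#' Fine-tune the last convolutional layers of an extractor
#'
#' Unfreezes the last `n_last_conv_layers` convolution layers of the
#' classifier's extractor and trains them jointly with the head using plain
#' SGD (learning rate within 0.001..0.01). Layers below the unfreezing point
#' stay byte-identical; their activations are precomputed once per split.
#' With `n_last_conv_layers = 0` the extractor is untouched and only the
#' head is updated.
#'
#' @param classifier A trained [acne_classifier()] with a conv extractor.
#' @param data A tagged [patch_set()].
#' @param n_last_conv_layers Number of trailing conv layers to unfreeze.
#' @param lr SGD learning rate in `[0.001, 0.01]`.
#' @param epochs Fine-tuning epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return List with `classifier` and `history` as in [train_classifier()].
#' @export
fine_tune <- function(classifier, data, n_last_conv_layers, lr = 0.001,
                      epochs = 5L, batch_size = 64L, seed = 1337L) {
  stopifnot(inherits(classifier, "acne_classifier"))
  if (is.null(classifier$extractor)) {
    stop("classifier has no convolutional extractor", call. = FALSE)
  }
  if (lr < 0.001 || lr > 0.01) {
    stop("`lr` must lie in [0.001, 0.01]", call. = FALSE)
  }
  ext <- classifier$extractor
  conv_idx <- which(vapply(ext$layers, function(ly) ly$kind == "conv", TRUE))
  if (n_last_conv_layers > length(conv_idx)) {
    stop("`n_last_conv_layers` exceeds the number of conv layers", call. = FALSE)
  }
  tr <- split_patches(data, "train")
  va <- split_patches(data, "val")
  config <- train_config("sgd", learning_rate = lr, momentum = 0,
                         batch_size = batch_size, epochs = epochs, seed = seed)
  if (n_last_conv_layers == 0L) {
    # head-only refinement; extractor weights untouched
    x_train <- extract_features(ext, tr, classifier$preproc)
    x_val <- extract_features(ext, va, classifier$preproc)
    fit <- fit_net(classifier$head, x_train, tr$labels, x_val, va$labels, config)
    classifier$head <- fit$net
    return(list(classifier = classifier, history = fit$history,
                best_epoch = fit$best_epoch))
  }
  cut <- conv_idx[length(conv_idx) - n_last_conv_layers + 1L]
  prefix <- ext$layers[seq_len(cut - 1L)]
  suffix <- ext$layers[seq(cut, length(ext$layers))]
  prefix_net <- structure(list(layers = prefix, input_shape = ext$input_shape,
                               kind = "frozen_prefix"), class = "cnn_net")
  # frozen prefix is static: compute its activations once per split
  pre_train <- forward_in_chunks(prefix_net, preprocess(tr$x, classifier$preproc))
  pre_val <- forward_in_chunks(prefix_net, preprocess(va$x, classifier$preproc))
  joint <- structure(list(layers = c(suffix, classifier$head$layers),
                          input_shape = suffix[[1]]$input_shape,
                          kind = "finetune_tail"), class = "cnn_net")
  fit <- fit_net(joint, pre_train, tr$labels, pre_val, va$labels, config)
  n_suffix <- length(suffix)
  ext$layers[seq(cut, length(ext$layers))] <- fit$net$layers[seq_len(n_suffix)]
  classifier$extractor <- ext
  classifier$head$layers <- fit$net$layers[-seq_len(n_suffix)]
  list(classifier = classifier, history = fit$history,
       best_epoch = fit$best_epoch)
}

# Chunked forward pass that may return 4-d conv activations.
forward_in_chunks <- function(net, x, chunk = 32L) {
  n <- dim(x)[4]
  first <- net_forward(net, x[, , , 1L, drop = FALSE], train = FALSE)
  starts <- if (n > 1L) seq(2L, n, by = chunk) else integer()
  if (is.matrix(first)) {
    out <- matrix(0, n, ncol(first))
    out[1L, ] <- first
    for (s in starts) {
      e <- min(n, s + chunk - 1L)
      out[s:e, ] <- net_forward(net, x[, , , s:e, drop = FALSE], train = FALSE)
    }
  } else {
    d <- dim(first)
    out <- array(0, c(d[1:3], n))
    out[, , , 1L] <- first
    for (s in starts) {
      e <- min(n, s + chunk - 1L)
      out[, , , s:e] <- net_forward(net, x[, , , s:e, drop = FALSE], train = FALSE)
    }
  }
  out
}

#' Write a per-epoch training log as CSV
#' @param history The `history` data frame from [train_classifier()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
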