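# Network specifications and the forward/backward engine.
#
# A net is a list of layer specs plus an input shape. Conv layers are 3x3,
# stride 1, zero-padded "same"; pooling is 2x2 stride 2 with either ceil- or
# floor-mode output sizes (the two pooling-rounding modes are forced by the
# printed widths of the two architectures: the small CNN must flatten to
# 10816 = 13*13*64, the headless VGG16 must collapse 50 -> 1 spatially).
#
# Tensor convention: conv-domain activations are (H, W, C, N) arrays,
# dense-domain activations are (N, D) matrices; `flatten` converts between
# them using R's natural column-major order (h fastest, then w, then c).

conv_layer <- function(filters, name = NULL, activation = "relu", ksize = 3L) {
  list(kind = "conv", filters = as.integer(filters), ksize = as.integer(ksize),
       activation = activation, name = name, trainable = TRUE)
}

maxpool_layer <- function(round = c("ceil", "floor"), name = NULL) {
  list(kind = "maxpool", round = match.arg(round), name = name)
}

dropout_layer <- function(rate = 0.5, name = NULL) {
  list(kind = "dropout", rate = rate, name = name)
}

flatten_layer <- function(name = NULL) list(kind = "flatten", name = name)

dense_layer <- function(units, activation = c("relu", "softmax", "linear"),
                        name = NULL) {
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation), name = name, trainable = TRUE)
}

# Propagate shapes through the layer list; records input/output shape per
# layer. Conv shapes are c(H, W, C); dense shapes are a single width.
infer_shapes <- function(layers, input_shape) {
  shape <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly$input_shape <- shape
    shape <- switch(ly$kind,
      conv = {
        if (length(shape) != 3L) stop("conv layer needs spatial input", call. = FALSE)
        c(shape[1], shape[2], ly$filters)
      },
      maxpool = {
        rd <- if (ly$round == "ceil") ceiling else floor
        c(rd(shape[1] / 2), rd(shape[2] / 2), shape[3])
      },
      dropout = shape,
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L) stop("dense layer needs flat input", call. = FALSE)
        ly$units
      }
    )
    ly$output_shape <- shape
    layers[[i]] <- ly
  }
  layers
}

#' Construct a network specification
#'
#' Low-level constructor used by [build_small_cnn()], [build_extractor()] and
#' [build_head()]; exposed so tests and experiments can assemble small custom
#' nets from the same layer primitives.
#'
#' @param layers List of layer specs (`conv_layer`, `maxpool_layer`,
#'   `dropout_layer`, `flatten_layer`, `dense_layer` — internal helpers).
#' @param input_shape `c(h, w, channels)` for convolutional nets or a single
#'   width for dense-only heads.
#' @param kind Free-form tag describing the architecture.
#' @return An object of class `cnn_net` (weights unset until
#'   [init_weights()]).
#' @export
cnn_net <- function(layers, input_shape, kind = "custom") {
  layers <- infer_shapes(layers, input_shape)
  structure(list(layers = layers, input_shape = input_shape, kind = kind),
            class = "cnn_net")
}

#' The self-constructed small CNN
#'
#' Two 64-filter conv layers, max-pool, one more 64-filter conv layer,
#' max-pool, dropout, flatten, a 128-unit ReLU dense layer, dropout, and a
#' softmax output. With 3x3 same-padded convolutions and ceil-mode 2x2
#' pooling the 50x50 input collapses 50 -> 25 -> 13, so the flatten width is
#' exactly 13 * 13 * 64 = 10816.
#'
#' @param n_classes Output width (default 2, the skin/non-skin detector).
#' @return A `cnn_net` (uninitialized).
#' @export
build_small_cnn <- function(n_classes = 2L) {
  cnn_net(list(
    conv_layer(64, "block1_conv1"),
    conv_layer(64, "block1_conv2"),
    maxpool_layer("ceil", "block1_pool"),
    conv_layer(64, "block2_conv1"),
    maxpool_layer("ceil", "block2_pool"),
    dropout_layer(0.5, "dropout1"),
    flatten_layer("flatten1"),
    dense_layer(128, "relu", "dense1"),
    dropout_layer(0.5, "dropout2"),
    dense_layer(n_classes, "softmax", "dense2")
  ), input_shape = c(50L, 50L, 3L), kind = "small_cnn")
}

#' Feature extractor specifications
#'
#' `vgg16_headless` is the 13-conv-layer VGG16 body (blocks of 2, 2, 3, 3, 3
#' convolutions with widths 64, 128, 256, 512, 512, each block ending in
#' 2x2 max pooling) without any classification head. With floor-mode pooling
#' a 50x50 input traces spatial sizes 25, 12, 6, 3, 1, ending at a 1x1x512
#' map that flattens to the 512-dimensional feature vector consumed by the
#' dense heads. Pre-trained weights can be attached via [load_weights()];
#' the extractor also runs (and is tested) with random initialization.
#'
#' `small_cnn_features` is the small CNN's convolutional stack plus flatten
#' (a 10816-wide descriptor).
#'
#' @param kind `"vgg16_headless"` or `"small_cnn_features"`.
#' @return A `cnn_net` (uninitialized).
#' @export
build_extractor <- function(kind = c("vgg16_headless", "small_cnn_features")) {
  kind <- match.arg(kind)
  if (kind == "vgg16_headless") {
    widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512))
    layers <- list()
    for (b in seq_along(widths)) {
      for (k in seq_along(widths[[b]])) {
        layers[[length(layers) + 1L]] <-
          conv_layer(widths[[b]][k], sprintf("block%d_conv%d", b, k))
      }
      layers[[length(layers) + 1L]] <-
        maxpool_layer("floor", sprintf("block%d_pool", b))
    }
    layers[[length(layers) + 1L]] <- flatten_layer("flatten")
    cnn_net(layers, c(50L, 50L, 3L), kind = "vgg16_headless")
  } else {
    cnn_net(list(
      conv_layer(64, "block1_conv1"),
      conv_layer(64, "block1_conv2"),
      maxpool_layer("ceil", "block1_pool"),
      conv_layer(64, "block2_conv1"),
      maxpool_layer("ceil", "block2_pool"),
      flatten_layer("flatten")
    ), c(50L, 50L, 3L), kind = "small_cnn_features")
  }
}

#' Dense classifier head
#'
#' Flatten(512) -> Dense(256, ReLU) -> Dropout -> Dense(n_classes) -> softmax.
#' The binary and seven-class heads differ only in the output width.
#'
#' @param n_classes 2 or 7.
#' @param feature_dim Input feature length (512 for the VGG16 extractor).
#' @return A `cnn_net` (uninitialized).
#' @export
build_head <- function(n_classes, feature_dim = 512L) {
  if (!n_classes %in% c(2L, 7L)) {
    stop("`n_classes` must be 2 or 7", call. = FALSE)
  }
  cnn_net(list(
    flatten_layer("flatten1"),
    dense_layer(256, "relu", "dense1"),
    dropout_layer(0.5, "dropout1"),
    dense_layer(n_classes, "softmax", "dense2")
  ), input_shape = as.integer(feature_dim),
  kind = sprintf("head_%d", n_classes))
}

#' Initialize network weights
#'
#' Conv kernels use He-uniform initialization (variance-preserving through
#' deep ReLU stacks); dense layers use Glorot-uniform. Biases start at zero.
#'
#' @param net A `cnn_net`.
#' @param seed Integer seed; identical seeds give identical weights.
#' @return The net with `W`/`b` set on every trainable layer.
#' @export
init_weights <- function(net, seed = 0L) {
  stopifnot(inherits(net, "cnn_net"))
  with_seed(seed, {
    for (i in seq_along(net$layers)) {
      ly <- net$layers[[i]]
      if (ly$kind == "conv") {
        fan_in <- ly$ksize^2 * ly$input_shape[3]
        limit <- sqrt(6 / fan_in)                     # He uniform
        ly$W <- matrix(runif(fan_in * ly$filters, -limit, limit),
                       fan_in, ly$filters)
        ly$b <- numeric(ly$filters)
      } else if (ly$kind == "dense") {
        fan_in <- ly$input_shape
        limit <- sqrt(6 / (fan_in + ly$units))        # Glorot uniform
        ly$W <- matrix(runif(fan_in * ly$units, -limit, limit),
                       fan_in, ly$units)
        ly$b <- numeric(ly$units)
      }
      net$layers[[i]] <- ly
    }
    net
  })
}

#' Save / load network weights
#'
#' Checkpoints are plain RDS files holding the layer weight list; the
#' architecture is carried alongside so a loaded net is self-contained.
#'
#' @param net An initialized `cnn_net`.
#' @param path Checkpoint path.
#' @return `save_weights` returns `path` invisibly; `load_weights` the net.
#' @export
save_weights <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "cnn_net"))
  net
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. `x` is (H, W, C, N) or (N, D) depending on the net's domain.
# With cache = TRUE, per-layer intermediates needed by net_backward are kept.
# Dropout is active only when train = TRUE (inverted dropout).
net_forward <- function(net, x, train = FALSE, cache = FALSE) {
  caches <- if (cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$kind == "conv") {
      xin <- x
      x <- conv2d_fw(x, ly$W, ly$b, identical(ly$activation, "relu"))
      if (cache) caches[[i]] <- list(x = xin, out = x)
    } else if (ly$kind == "maxpool") {
      d <- dim(x)
      res <- maxpool2_fw(x, ly$round == "ceil")
      x <- res$out
      if (cache) caches[[i]] <- list(idx = res$idx, H = d[1], W = d[2])
    } else if (ly$kind == "dropout") {
      if (train) {
        keep <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
        dim(keep) <- dim(x)
        x <- x * keep
        if (cache) caches[[i]] <- list(mask = keep)
      }
    } else if (ly$kind == "flatten") {
      if (!is.matrix(x)) {
        d <- dim(x)
        if (cache) caches[[i]] <- list(dims = d)
        x <- t(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
      }
    } else if (ly$kind == "dense") {
      xin <- x
      z <- x %*% ly$W
      z <- sweep(z, 2, ly$b, "+")
      x <- switch(ly$activation,
        relu = pmax(z, 0),
        softmax = softmax_rows(z),
        linear = z
      )
      if (cache) caches[[i]] <- list(x = xin, out = x)
    }
  }
  if (cache) list(out = x, caches = caches) else x
}

# Backward pass. `dtop` is the gradient at the pre-activation of the final
# softmax dense layer (i.e. probs - onehot, averaged over the batch) — the
# usual fused softmax + cross-entropy gradient. Returns per-layer gradients.
net_backward <- function(net, caches, dtop) {
  grads <- vector("list", length(net$layers))
  d <- dtop
  first_trainable <- Position(function(ly) isTRUE(ly$trainable), net$layers)
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$kind == "dense") {
      dz <- if (identical(ly$activation, "relu")) d * (ca$out > 0) else d
      grads[[i]] <- list(dW = crossprod(ca$x, dz), db = colSums(dz))
      d <- tcrossprod(dz, ly$W)
    } else if (ly$kind == "dropout") {
      if (!is.null(ca)) d <- d * ca$mask
    } else if (ly$kind == "flatten") {
      if (!is.null(ca)) {
        d <- array(t(d), ca$dims)
      }
    } else if (ly$kind == "maxpool") {
      d <- maxpool2_bw(d, ca$idx, ca$H, ca$W)
    } else if (ly$kind == "conv") {
      res <- conv2d_bw(ca$x, ly$W, ca$out, d,
                       identical(ly$activation, "relu"),
                       need_dx = i > first_trainable)
      grads[[i]] <- list(dW = res$dW, db = res$db)
      d <- res$dx
      if (i == first_trainable) break
    }
  }
  grads
}

#' Count trainable parameters
#' @param net A `cnn_net`.
#' @return Total number of weights and biases the net would train.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "cnn_net"))
  tot <- 0
  for (ly in net$layers) {
    if (ly$kind == "conv") {
      tot <- tot + ly$ksize^2 * ly$input_shape[3] * ly$filters + ly$filters
    } else if (ly$kind == "dense") {
      tot <- tot + ly$input_shape * ly$units + ly$units
    }
  }
  tot
}

#' Summarize a network
#'
#' @param net A `cnn_net`.
#' @param path Optional path: when given, the summary is written as JSON
#'   (layer name, type, output shape).
#' @return A data frame with one row per layer.
#' @export
model_summary <- function(net, path = NULL) {
  stopifnot(inherits(net, "cnn_net"))
  df <- data.frame(
    name = vapply(net$layers, function(ly) ly$name %||% ly$kind, ""),
    type = vapply(net$layers, function(ly) ly$kind, ""),
    output_shape = vapply(net$layers, function(ly)
      paste(ly$output_shape, collapse = "x"), ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cnn_net <- function(x, ...) {
  cat(sprintf("<cnn_net> %s, input %s, %s parameters\n", x$kind,
              paste(x$input_shape, collapse = "x"),
              format(n_params(x), big.mark = ",")))
  print(model_summary(x))
  invisible(x)
}

#' Extract feature vectors from patches
#'
#' Preprocesses the patches per `preproc` and runs them through the
#' extractor, returning one descriptor row per patch (512 columns for the
#' headless VGG16), order preserved. Runs in chunks to bound memory.
#'
#' @param extractor An initialized extractor `cnn_net`.
#' @param patches A [patch_set()] or a `(50, 50, 3, n)` array of raw pixels.
#' @param preproc A [preproc_spec()].
#' @param chunk Patches per forward chunk.
#' @return An `n x feature_dim` numeric matrix.
#' @export
extract_features <- function(extractor, patches, preproc, chunk = 32L) {
  x <- if (inherits(patches, "patch_set")) patches$x else patches
  if (length(dim(x)) != 4L) stop("`patches` must be a 4-d array or patch_set", call. = FALSE)
  n <- dim(x)[4]
  fdim <- utils::tail(extractor$layers, 1)[[1]]$output_shape
  out <- matrix(0, n, fdim)
  if (n == 0L) return(out)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    xb <- preprocess(x[, , , s:e, drop = FALSE], preproc)
    out[s:e, ] <- net_forward(extractor, xb, train = FALSE)
  }
  out
}

#' Bundle an extractor, head and preprocessing into a classifier
#'
#' A trained classifier carries everything needed to score new patches: an
#' optional convolutional feature extractor, the dense head (or, when
#' `extractor` is `NULL`, a full end-to-end CNN), the preprocessing spec its
#' training data used, the class vocabulary, and — for binary classifiers —
#' the decision threshold on the positive-class probability.
#'
#' @param head A `cnn_net` whose final layer is softmax.
#' @param preproc A [preproc_spec()].
#' @param class_names Character vector matching the head's output width.
#' @param extractor Optional frozen `cnn_net` feature extractor.
#' @param threshold Optional decision threshold in (0, 1).
#' @return An object of class `acne_classifier`.
#' @export
acne_classifier <- function(head, preproc, class_names, extractor = NULL,
                            threshold = NULL) {
  stopifnot(inherits(head, "cnn_net"), inherits(preproc, "preproc_spec"))
  out_w <- utils::tail(head$layers, 1)[[1]]$output_shape
  if (length(class_names) != out_w) {
    stop("`class_names` length must match the head output width", call. = FALSE)
  }
  if (!is.null(threshold) && (threshold <= 0 || threshold >= 1)) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(extractor = extractor, head = head, preproc = preproc,
                 class_names = as.character(class_names),
                 threshold = threshold),
            class = "acne_classifier")
}

#' Score patches with a classifier
#'
#' @param object An `acne_classifier`.
#' @param patches A [patch_set()] or `(50, 50, 3, n)` array of raw pixels.
#' @param chunk Patches per forward chunk.
#' @param ... Unused.
#' @return An `n x k` matrix of class probabilities (rows sum to 1), columns
#'   named by the class vocabulary.
#' @export
predict.acne_classifier <- function(object, patches, chunk = 32L, ...) {
  x <- if (inherits(patches, "patch_set")) patches$x else patches
  if (!is.null(object$extractor)) {
    feats <- extract_features(object$extractor, x, object$preproc, chunk)
    probs <- net_forward(object$head, feats, train = FALSE)
  } else {
    n <- dim(x)[4]
    k <- utils::tail(object$head$layers, 1)[[1]]$output_shape
    probs <- matrix(0, n, k)
    if (n == 0L) {
      colnames(probs) <- object$class_names
      return(probs)
    }
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      xb <- preprocess(x[, , , s:e, drop = FALSE], object$preproc)
      probs[s:e, ] <- net_forward(object$head, xb, train = FALSE)
    }
  }
  colnames(probs) <- object$class_names
  probs
}

#' @export
print.acne_classifier <- function(x, ...) {
  cat(sprintf("<acne_classifier> classes: %s\n",
              paste(x$class_names, collapse = ", ")))
  if (!is.null(x$extractor)) {
    cat(sprintf("  extractor: %s (%s params)\n", x$extractor$kind,
                format(n_params(x$extractor), big.mark = ",")))
  }
  cat(sprintf("  head: %s (%s params)\n", x$head$kind,
              format(n_params(x$head), big.mark = ",")))
  cat(sprintf("  preprocessing: %s\n", x$preproc$mode))
  if (!is.null(x$threshold)) {
    cat(sprintf("  decision threshold: %.3f\n", x$threshold))
  }
  invisible(x)
}
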