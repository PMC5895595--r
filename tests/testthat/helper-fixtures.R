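# Shared fixtures. Heavy models (the acceptance-scale classifiers) are
# trained once per test run and memoized here so several test files can
# reuse them.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small random conv extractor: cheap stand-in wherever a test only needs
# "some" differentiable feature map, not the full VGG16 cost.
tiny_extractor <- function(seed = 11) {
  ns <- asNamespace("acnescan")
  net <- cnn_net(list(
    ns$conv_layer(16, "c1"),
    ns$maxpool_layer("floor", "p1"),
    ns$conv_layer(16, "c2"),
    ns$maxpool_layer("floor", "p2"),
    ns$maxpool_layer("floor", "p3"),
    ns$flatten_layer("flatten")
  ), input_shape = c(50L, 50L, 3L), kind = "tiny_features")
  init_weights(net, seed)
}

tiny_head <- function(n_classes, feature_dim, seed = 12) {
  ns <- asNamespace("acnescan")
  net <- cnn_net(list(
    ns$flatten_layer(),
    ns$dense_layer(64, "relu", "d1"),
    ns$dense_layer(n_classes, "softmax", "d2")
  ), input_shape = as.integer(feature_dim), kind = "tiny_head")
  init_weights(net, seed)
}

# Binary skin/non-skin classifier at the study scale: 200 patches per class,
# small CNN trained 20 epochs with the protocol seed, threshold calibrated
# on the validation split by Youden's index.
acceptance_binary <- function() {
  get_fixture("acceptance_binary", function() {
    ps <- split_patchset(gen_patchset(200, skin_classes(), seed = 1337),
                         seed = 1337)
    net <- init_weights(build_small_cnn(2), seed = 1337)
    clf <- acne_classifier(net, preproc_spec("rescale_01"), skin_classes())
    fit <- train_classifier(clf, ps,
                            train_config("adam", epochs = 20, seed = 1337))
    list(classifier = calibrate_threshold(fit$classifier, ps),
         data = ps, fit = fit)
  })
}

# Seven-class lesion classifier at the study scale: small CNN with a 7-way
# softmax trained end to end for 12 epochs on standardized pixels.
acceptance_seven <- function() {
  get_fixture("acceptance_seven", function() {
    ps <- split_patchset(gen_patchset(200, acne_classes(), seed = 7),
                         seed = 1337)
    pre <- preproc_from_data(split_patches(ps, "train")$x)
    net <- init_weights(build_small_cnn(7), seed = 1337)
    clf <- acne_classifier(net, pre, acne_classes())
    fit <- train_classifier(clf, ps,
                            train_config("adam", epochs = 12, seed = 1337))
    list(classifier = fit$classifier, data = ps, fit = fit)
  })
}

# Exhaustive pair-count AUC: concordant positive/negative score pairs with
# half credit for ties — the Mann-Whitney oracle, independent of the
# trapezoid path.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every distinct-score cut (>= convention).
youden_scan_oracle <- function(scores, labels) {
  cuts <- sort(unique(c(scores, Inf)), decreasing = TRUE)
  best_j <- -Inf; best_t <- Inf
  for (t in cuts) {
    pred <- scores >= t
    sen <- sum(pred & labels == 1) / sum(labels == 1)
    fpr <- sum(pred & labels == 0) / sum(labels == 0)
    j <- sen - fpr
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && t < best_t)) {
      best_j <- j; best_t <- t
    }
  }
  list(youden_j = best_j, best_threshold = best_t)
}

# The six worked probability vectors and their printed symptom sets.
symptom_examples <- function() {
  list(
    a = list(p = c(0.00, 0.00, 0.01, 0.61, 0.13, 0.21, 0.03), out = c("c4", "c5")),
    b = list(p = c(0.32, 0.04, 0.08, 0.30, 0.08, 0.16, 0.02), out = c("c0", "c5")),
    c = list(p = c(0.14, 0.08, 0.16, 0.36, 0.22, 0.00, 0.04), out = c("c0", "c2", "c4")),
    d = list(p = c(0.28, 0.41, 0.03, 0.00, 0.11, 0.08, 0.09), out = c("c0", "c1", "c4")),
    e = list(p = c(0.04, 0.04, 0.32, 0.42, 0.07, 0.06, 0.04), out = "c2"),
    f = list(p = c(0.11, 0.26, 0.04, 0.06, 0.26, 0.04, 0.23), out = c("c1", "c4", "c6"))
  )
}
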