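# Splitting, losses, the training loop, fine-tuning.

test_that("stratified splitting uses exact largest-remainder arithmetic", {
  labels <- rep(1:2, each = 120)
  tags <- split_indices(labels, c(0.8, 0.1, 0.1), seed = 3)
  for (cl in 1:2) {
    expect_equal(as.vector(table(tags[labels == cl])[c("train", "val", "test")]),
                 c(96L, 12L, 12L))
  }
  # same seed -> identical assignment; splits partition the set
  expect_identical(tags, split_indices(labels, c(0.8, 0.1, 0.1), seed = 3))
  expect_false(identical(tags, split_indices(labels, c(0.8, 0.1, 0.1), seed = 4)))
  ps <- split_patchset(gen_patchset(20, skin_classes(), 1), seed = 5)
  parts <- lapply(c("train", "val", "test"), function(tg) which(ps$split == tg))
  expect_equal(sort(unlist(parts)), 1:40)
  expect_warning(split_indices(rep(1, 8), seed = 1), "proportional rounding")
})

test_that("binary cross entropy matches its closed forms", {
  expect_equal(binary_ce(0.5, 0), log(2))
  expect_equal(binary_ce(0.5, 1), log(2))
  expect_equal(binary_ce(0.9, 0), -log(0.1))
  expect_lt(binary_ce(1 - 1e-9, 1), 1e-6)
  set.seed(10)
  p <- runif(100, 0.01, 0.99); t <- rbinom(100, 1, 0.5)
  # independent evaluation straight from the definition
  expect_equal(binary_ce(p, t), ifelse(t == 1, -log(p), -log(1 - p)),
               tolerance = 1e-10)
  expect_error(binary_ce(0.5, 2), "0/1")
})

test_that("categorical cross entropy matches its closed forms", {
  onehot <- function(i) { v <- numeric(7); v[i] <- 1; v }
  expect_equal(categorical_ce(onehot(3), onehot(3)), 0, tolerance = 1e-6)
  expect_equal(categorical_ce(rep(1 / 7, 7), onehot(2)), log(7))
  set.seed(11)
  for (i in 1:100) {
    y <- runif(7); y <- y / sum(y)
    k <- sample(7, 1)
    expect_equal(categorical_ce(y, onehot(k)), -log(y[k]), tolerance = 1e-10)
  }
  # loss strictly decreases as the correct-class probability rises
  ys <- t(sapply(seq(0.2, 0.9, by = 0.1), function(q) c(q, rep((1 - q) / 6, 6))))
  ls <- categorical_ce(ys, matrix(rep(onehot(1), nrow(ys)), ncol = 7, byrow = TRUE))
  expect_true(all(diff(ls) < 0))
  expect_error(categorical_ce(c(0.5, 0.6, rep(0, 5)), onehot(1)), "normalized")
})

make_tiny_task <- function(n_per_class, data_seed, shuffle_labels = FALSE) {
  ps <- gen_patchset(n_per_class, skin_classes(), seed = data_seed)
  if (shuffle_labels) {
    ps$labels <- local({ set.seed(99); sample(ps$labels) })
  }
  split_patchset(ps, seed = 21)
}

tiny_classifier <- function(seed = 12) {
  ext <- tiny_extractor()
  fdim <- ext$layers[[length(ext$layers)]]$output_shape
  acne_classifier(tiny_head(2, fdim, seed), preproc_spec("rescale_01"),
                  skin_classes(), extractor = ext)
}

test_that("training a head on separable fixtures reaches high validation accuracy", {
  data <- make_tiny_task(200, 31)
  # fixture sanity: a logistic regression on low-order color statistics
  # (channel means and sds) already separates the two classes
  feats <- t(apply(data$x, 4, function(a) {
    m <- matrix(a, ncol = 3)
    c(colMeans(m), apply(m, 2, sd))
  }))
  df <- data.frame(y = as.integer(data$labels == 1), feats)
  fit0 <- suppressWarnings(glm(y ~ ., df[data$split == "train", ], family = binomial()))
  pr <- predict(fit0, df[data$split == "val", ], type = "response")
  expect_gte(mean((pr > 0.5) == df$y[data$split == "val"]), 0.95)

  cfg <- train_config("adam", epochs = 15, batch_size = 64, seed = 1337)
  fit <- train_classifier(tiny_classifier(), data, cfg)
  expect_equal(nrow(fit$history), 15L)
  expect_gte(fit$history$val_acc[which.max(fit$history$val_acc)], 0.95)
  expect_equal(fit$best_epoch, which.max(fit$history$val_acc))
})

test_that("training is deterministic for a fixed config and data", {
  data <- make_tiny_task(40, 32)
  cfg <- train_config("adam", epochs = 3, batch_size = 16, seed = 1337)
  f1 <- train_classifier(tiny_classifier(), data, cfg)
  f2 <- train_classifier(tiny_classifier(), data, cfg)
  expect_identical(f1$best_epoch, f2$best_epoch)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-6)
  expect_equal(f1$history$val_loss, f2$history$val_loss, tolerance = 1e-6)
})

test_that("label-shuffled training stays near chance validation accuracy", {
  data <- make_tiny_task(200, 33, shuffle_labels = TRUE)
  cfg <- train_config("adam", epochs = 5, batch_size = 64, seed = 1337)
  fit <- train_classifier(tiny_classifier(), data, cfg)
  acc <- fit$history$val_acc[nrow(fit$history)]
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("fine-tuning freezes exactly the requested prefix", {
  data <- make_tiny_task(30, 34)
  cfg <- train_config("adam", epochs = 2, batch_size = 16, seed = 1337)
  fit <- train_classifier(tiny_classifier(), data, cfg)
  clf <- fit$classifier
  conv_idx <- which(vapply(clf$extractor$layers,
                           function(ly) ly$kind == "conv", TRUE))
  # n = 0: extractor byte-identical
  ft0 <- fine_tune(clf, data, 0, lr = 0.001, epochs = 1, seed = 2)
  expect_identical(ft0$classifier$extractor, clf$extractor)
  # n = 1: first conv frozen, last conv and head move
  ft1 <- fine_tune(clf, data, 1, lr = 0.005, epochs = 2, seed = 2)
  first <- conv_idx[1]; last <- conv_idx[length(conv_idx)]
  expect_identical(ft1$classifier$extractor$layers[[first]]$W,
                   clf$extractor$layers[[first]]$W)
  expect_false(identical(ft1$classifier$extractor$layers[[last]]$W,
                         clf$extractor$layers[[last]]$W))
  expect_error(fine_tune(clf, data, 99, lr = 0.005), "exceeds")
  expect_error(fine_tune(clf, data, 1, lr = 0.5), "lr")
})

test_that("gentle fine-tuning does not degrade validation accuracy at desk scale", {
  data <- make_tiny_task(100, 35)
  cfg <- train_config("adam", epochs = 8, batch_size = 64, seed = 1337)
  fit <- train_classifier(tiny_classifier(), data, cfg)
  before <- max(fit$history$val_acc)
  ft <- fine_tune(fit$classifier, data, 1, lr = 0.001, epochs = 3, seed = 3)
  after <- max(ft$history$val_acc)
  expect_gte(after, before - 0.02)
})

test_that("the training log writes one CSV row per epoch", {
  data <- make_tiny_task(20, 36)
  cfg <- train_config("adam", epochs = 2, batch_size = 16, seed = 1)
  fit <- train_classifier(tiny_classifier(), data, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_log(fit$history, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_acc") %in% names(back)))
})
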