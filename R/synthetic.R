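# Synthetic patch and face generator.
#
# Clinical acne photographs are private; these recipes stand in for them so
# that every downstream stage (augmentation, training, evaluation, whole-face
# diagnosis) is testable without any download. Classes are deliberately
# separable by low-order color/shape statistics so that small CPU-trained
# networks can learn them. All recipes are synthetic stand-ins, not
# photorealistic lesion models.

GEN_CLASSES <- c("skin", "non_skin", "c0", "c1", "c2", "c3", "c4", "c5", "c6")

# Boolean disc mask on the 50x50 grid: pixels with (r-cy)^2 + (c-cx)^2 <= r^2.
disc_mask <- function(cy, cx, r, side = PATCH_SIDE) {
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# Beige skin base: R ~ 200, G ~ 160, B ~ 140, i.i.d. per-pixel noise sd 10.
skin_base <- function(side = PATCH_SIDE) {
  base <- c(200, 160, 140)
  px <- array(0, c(side, side, 3L))
  for (ch in 1:3) px[, , ch] <- base[ch] + rnorm(side * side, 0, 10)
  px
}

# Overlay a noisy colored region where `mask` is TRUE.
paint <- function(px, mask, color, sd = 8, lo = 0, hi = 255) {
  n <- sum(mask)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- clamp(color[ch] + rnorm(n, 0, sd), lo, hi)
    px[, , ch] <- plane
  }
  px
}

# A lesion-free patch: skin base only.
recipe_skin <- function() skin_base()

# The binary task's skin class covers both normal and diseased facial skin,
# so its recipe is a 50/50 mixture of the plain base and a uniformly drawn
# lesion overlay — otherwise a skin detector trained on it would reject
# every lesion tile as out-of-distribution.
recipe_skin_mixture <- function() {
  if (runif(1) < 0.5) return(recipe_skin())
  switch(sample(c("c0", "c1", "c2", "c4", "c5", "c6"), 1),
         c0 = recipe_c0(), c1 = recipe_c1(), c2 = recipe_c2(),
         c4 = recipe_c4(), c5 = recipe_c5(), c6 = recipe_c6())
}

# Dark hair texture: high-frequency sinusoidal stripes, all channels < 80.
recipe_hair <- function(side = PATCH_SIDE) {
  ang <- runif(1, 0, pi)
  freq <- runif(1, 0.25, 0.6)          # cycles per pixel: high frequency
  phase <- runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  stripe <- 35 + 25 * sin(2 * pi * freq * (rows * cos(ang) + cols * sin(ang)) + phase)
  px <- array(0, c(side, side, 3L))
  for (ch in 1:3) px[, , ch] <- clamp(stripe + rnorm(side * side, 0, 4), 0, 79)
  px
}

# Saturated uniform background of a random hue.
recipe_background <- function(side = PATCH_SIDE) {
  hue <- runif(1)
  rgb <- as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 0.85, 0.9)))
  px <- array(0, c(side, side, 3L))
  for (ch in 1:3) px[, , ch] <- rgb[ch] + rnorm(side * side, 0, 3)
  px
}

recipe_non_skin <- function() {
  if (runif(1) < 0.5) recipe_hair() else recipe_background()
}

# Lesion overlays on skin base. Radii are sampled in the documented ranges;
# centers stay at least one radius from the border so discs are not clipped
# (the nodule is the exception: it may touch edges but keeps > 40% coverage).
recipe_c0 <- function() {           # papule: small red disc
  px <- skin_base()
  r <- sample(5:8, 1)
  cy <- sample((r + 1):(PATCH_SIDE - r), 1)
  cx <- sample((r + 1):(PATCH_SIDE - r), 1)
  paint(px, disc_mask(cy, cx, r), c(205, 80, 90))
}

recipe_c1 <- function() {           # cyst: large dark-red disc
  px <- skin_base()
  r <- sample(15:20, 1)
  cy <- sample((r + 1):(PATCH_SIDE - r), 1)
  cx <- sample((r + 1):(PATCH_SIDE - r), 1)
  paint(px, disc_mask(cy, cx, r), c(130, 45, 55))
}

recipe_c2 <- function() {           # blackhead: 1-3 dark dots
  px <- skin_base()
  ndots <- sample(1:3, 1)
  for (i in seq_len(ndots)) {
    r <- sample(2:3, 1)
    cy <- sample((r + 1):(PATCH_SIDE - r), 1)
    cx <- sample((r + 1):(PATCH_SIDE - r), 1)
    px <- paint(px, disc_mask(cy, cx, r), c(30, 30, 30), sd = 5, hi = 55)
  }
  px
}

recipe_c4 <- function() {           # pustule: red disc with white center
  px <- skin_base()
  r <- sample(5:8, 1)
  cy <- sample((r + 1):(PATCH_SIDE - r), 1)
  cx <- sample((r + 1):(PATCH_SIDE - r), 1)
  px <- paint(px, disc_mask(cy, cx, r), c(205, 80, 90))
  paint(px, disc_mask(cy, cx, sample(2:3, 1)), c(240, 235, 225), sd = 5)
}

recipe_c5 <- function() {           # whitehead: small white dot
  px <- skin_base()
  r <- sample(2:3, 1)
  cy <- sample((r + 1):(PATCH_SIDE - r), 1)
  cx <- sample((r + 1):(PATCH_SIDE - r), 1)
  paint(px, disc_mask(cy, cx, r), c(240, 238, 230), sd = 5)
}

recipe_c6 <- function() {           # nodule: large low-contrast dark-red region
  px <- skin_base()
  r <- sample(19:23, 1)
  cy <- 25 + sample(-3:3, 1)
  cx <- 25 + sample(-3:3, 1)
  paint(px, disc_mask(cy, cx, r), c(165, 115, 110))
}

#' Generate one synthetic 50x50 labeled patch
#'
#' Each class id maps to a deterministic recipe given the seed: `c3` is
#' plain beige skin; `skin` (the binary task's positive class, which covers
#' normal and diseased facial skin) is a 50/50 mixture of the plain base and
#' a uniformly drawn lesion overlay; `non_skin` is dark hair texture or a
#' saturated uniform background (50/50); `c0`..`c6` overlay the
#' corresponding lesion signature on a skin base. Pixel values are integers
#' in 0..255.
#'
#' @param class_id One of `"skin"`, `"non_skin"`, `"c0"`..`"c6"`.
#' @param seed Integer seed; identical `(class_id, seed)` pairs give
#'   bit-identical patches.
#' @return A 50x50x3 numeric array (integer-valued) with attribute `label`.
#' @export
gen_patch <- function(class_id, seed) {
  if (!is.character(class_id) || length(class_id) != 1L ||
      !class_id %in% GEN_CLASSES) {
    stop(sprintf("unknown class id %s; must be one of %s",
                 deparse(class_id), paste(GEN_CLASSES, collapse = ", ")),
         call. = FALSE)
  }
  px <- with_seed(seed, switch(class_id,
    skin = recipe_skin_mixture(),
    c3 = recipe_skin(),
    non_skin = recipe_non_skin(),
    c0 = recipe_c0(),
    c1 = recipe_c1(),
    c2 = recipe_c2(),
    c4 = recipe_c4(),
    c5 = recipe_c5(),
    c6 = recipe_c6()
  ))
  px <- round(clamp(px, 0, 255))
  attr(px, "label") <- class_id
  px
}

#' Generate a balanced labeled patch set
#'
#' @param n_per_class Patches per class (>= 1).
#' @param classes Class vocabulary, e.g. [skin_classes()] or [acne_classes()].
#' @param seed Integer seed; the set is reproducible bit-for-bit.
#' @return A [patch_set()] with `n_per_class * length(classes)` patches.
#' @export
gen_patchset <- function(n_per_class, classes, seed) {
  stopifnot_scalar_number(n_per_class, "n_per_class")
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (!all(classes %in% GEN_CLASSES)) {
    stop("unknown class id in `classes`", call. = FALSE)
  }
  n <- as.integer(n_per_class) * length(classes)
  x <- array(0, c(PATCH_SIDE, PATCH_SIDE, 3L, n))
  labels <- integer(n)
  i <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      # distinct sub-seed per patch keeps patches independent yet reproducible
      x[, , , i] <- gen_patch(classes[ci], seed + 131L * (i - 1L))
      labels[i] <- ci
    }
  }
  patch_set(x, labels, classes)
}

#' Assemble a synthetic 500x500 face image from a tile recipe grid
#'
#' The image is built by placing `gen_patch(tile_truth[r, c])` at each tile of
#' a 10x10 grid, row-major, with the per-tile seed `seed + (r-1)*10 + (c-1)`,
#' so faces are reproducible tile by tile.
#'
#' @param tile_truth 10x10 character matrix over `skin`, `non_skin`,
#'   `c0`..`c6` — the ground-truth class of each 50x50 tile.
#' @param seed Integer seed.
#' @return An object of class `face_fixture`: list with `image`
#'   (500x500x3 array), `tile_truth`, and `recipe_seed`.
#' @export
gen_face <- function(tile_truth, seed) {
  if (!is.matrix(tile_truth) || nrow(tile_truth) != 10L || ncol(tile_truth) != 10L) {
    stop("`tile_truth` must be a 10x10 matrix of class ids", call. = FALSE)
  }
  if (!all(tile_truth %in% GEN_CLASSES)) {
    stop("unknown class id in `tile_truth`", call. = FALSE)
  }
  side <- PATCH_SIDE
  img <- array(0, c(10L * side, 10L * side, 3L))
  for (r in 1:10) {
    for (cc in 1:10) {
      tile <- gen_patch(tile_truth[r, cc], seed + (r - 1L) * 10L + (cc - 1L))
      img[(r - 1L) * side + seq_len(side), (cc - 1L) * side + seq_len(side), ] <- tile
    }
  }
  structure(list(image = img, tile_truth = tile_truth, recipe_seed = seed),
            class = "face_fixture")
}

#' @export
print.face_fixture <- function(x, ...) {
  cat(sprintf("<face_fixture> %dx%d image, seed %d\n",
              dim(x$image)[1], dim(x$image)[2], x$recipe_seed))
  print(table(x$tile_truth))
  invisible(x)
}
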