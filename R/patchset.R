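# Patch and patch-set containers plus PNG/CSV interchange.

PATCH_SIDE <- 50L

#' Class vocabularies
#'
#' The seven lesion/skin classes used by the seven-class classifier, and the
#' two classes used by the skin/non-skin detector. The seven-class order is
#' fixed: papule (c0), cyst (c1), blackhead (c2), normal skin (c3), pustule
#' (c4), whitehead (c5), nodule (c6).
#'
#' @return A character vector of class ids.
#' @export
acne_classes <- function() {
  c("c0", "c1", "c2", "c3", "c4", "c5", "c6")
}

#' @rdname acne_classes
#' @export
skin_classes <- function() {
  c("skin", "non_skin")
}

#' Long names for the seven lesion classes
#' @return Named character vector mapping class id to lesion name.
#' @export
acne_class_names <- function() {
  c(c0 = "papule", c1 = "cyst", c2 = "blackhead", c3 = "normal skin",
    c4 = "pustule", c5 = "whitehead", c6 = "nodule")
}

#' Construct a patch set
#'
#' A patch set is the atomic data container of the pipeline: an ordered
#' collection of 50x50 RGB patches with integer labels into a class
#' vocabulary and optional train/val/test split tags.
#'
#' @param x Numeric array of dim `c(50, 50, 3, n)`, values in 0..255.
#' @param labels Integer vector of length `n`, 1-based indices into
#'   `class_names`.
#' @param class_names Character vector, the ordered label vocabulary.
#' @param split Optional character vector of length `n` with values
#'   `"train"`, `"val"`, `"test"` or `NA` (unassigned).
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(x, labels, class_names, split = NULL) {
  d <- dim(x)
  if (length(d) != 4L || d[1] != PATCH_SIDE || d[2] != PATCH_SIDE || d[3] != 3L) {
    stop("`x` must be a 50 x 50 x 3 x n array", call. = FALSE)
  }
  if (length(x) && (min(x) < 0 || max(x) > 255)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != d[4]) {
    stop("one label per patch required", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 1L | labels > length(class_names))) {
    stop("every label must index `class_names`", call. = FALSE)
  }
  if (!is.null(split)) {
    if (length(split) != d[4]) stop("one split tag per patch required", call. = FALSE)
    bad <- !is.na(split) & !split %in% c("train", "val", "test")
    if (any(bad)) stop("split tags must be train/val/test or NA", call. = FALSE)
  }
  structure(
    list(x = x, labels = labels, class_names = as.character(class_names),
         split = split),
    class = "patch_set"
  )
}

#' Number of patches in a patch set
#' @param set A `patch_set`.
#' @return Integer count.
#' @export
n_patches <- function(set) {
  stopifnot(inherits(set, "patch_set"))
  dim(set$x)[4]
}

#' @export
print.patch_set <- function(x, ...) {
  n <- n_patches(x)
  cat(sprintf("<patch_set> %d patches, %d classes (%s)\n",
              n, length(x$class_names), paste(x$class_names, collapse = ", ")))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  print(tab)
  if (!is.null(x$split)) {
    cat("split:\n")
    print(table(x$split, useNA = "ifany"))
  }
  invisible(x)
}

#' Subset a patch set
#'
#' @param set A `patch_set`.
#' @param idx Integer or logical index vector over patches.
#' @return A `patch_set` with the selected patches (split tags retained).
#' @export
subset_patches <- function(set, idx) {
  stopifnot(inherits(set, "patch_set"))
  patch_set(set$x[, , , idx, drop = FALSE], set$labels[idx], set$class_names,
            split = if (!is.null(set$split)) set$split[idx])
}

#' Extract the patches carrying a given split tag
#' @param set A tagged `patch_set`.
#' @param tag One of `"train"`, `"val"`, `"test"`.
#' @return A `patch_set`.
#' @export
split_patches <- function(set, tag = c("train", "val", "test")) {
  tag <- match.arg(tag)
  if (is.null(set$split)) stop("patch set has no split tags", call. = FALSE)
  subset_patches(set, which(!is.na(set$split) & set$split == tag))
}

#' Write a patch set as per-class directories of PNG files
#'
#' Creates one subdirectory per class under `dir` and writes each patch as
#' `patch_NNNNN.png`. The inverse is [read_patchset()].
#'
#' @param set A `patch_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patchset <- function(set, dir) {
  stopifnot(inherits(set, "patch_set"))
  for (ci in seq_along(set$class_names)) {
    cdir <- file.path(dir, set$class_names[ci])
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    idx <- which(set$labels == ci)
    for (j in seq_along(idx)) {
      img <- set$x[, , , idx[j]] / 255
      png::writePNG(img, file.path(cdir, sprintf("patch_%05d.png", j)))
    }
  }
  invisible(dir)
}

#' Read a patch set written by [write_patchset()]
#'
#' @param dir Directory holding one subdirectory of PNG files per class.
#' @param class_names Optional vocabulary order; defaults to the sorted
#'   subdirectory names.
#' @return A `patch_set`.
#' @export
read_patchset <- function(dir, class_names = NULL) {
  if (is.null(class_names)) {
    class_names <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  }
  if (length(class_names) == 0L) stop("no class subdirectories found", call. = FALSE)
  xs <- list(); labels <- integer()
  for (ci in seq_along(class_names)) {
    files <- sort(list.files(file.path(dir, class_names[ci]),
                             pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
      img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
      xs[[length(xs) + 1L]] <- round(img * 255)
      labels <- c(labels, ci)
    }
  }
  if (length(xs) == 0L) stop("no PNG patches found", call. = FALSE)
  x <- array(0, c(PATCH_SIDE, PATCH_SIDE, 3L, length(xs)))
  for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
  patch_set(x, labels, class_names)
}

#' Write / read a face fixture's ground-truth tile grid as CSV
#'
#' The CSV has columns `row`, `col` (0-based tile coordinates) and `class`.
#'
#' @param tile_truth A 10x10 character matrix of class ids.
#' @param path CSV path.
#' @return `path` invisibly; `read_tile_truth()` returns the matrix.
#' @export
write_tile_truth <- function(tile_truth, path) {
  df <- data.frame(
    row = rep(seq_len(nrow(tile_truth)) - 1L, each = ncol(tile_truth)),
    col = rep(seq_len(ncol(tile_truth)) - 1L, times = nrow(tile_truth)),
    class = as.vector(t(tile_truth))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_truth
#' @export
read_tile_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nr <- max(df$row) + 1L; nc <- max(df$col) + 1L
  m <- matrix(NA_character_, nr, nc)
  m[cbind(df$row + 1L, df$col + 1L)] <- df$class
  m
}
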