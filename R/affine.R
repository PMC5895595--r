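# Affine augmentation matrices, resampling, and preprocessing.
#
# Coordinates are (row, col) with 1-based pixel centers; the image center is
# ((h+1)/2, (w+1)/2) and is a fixed point of the rotation, shear and zoom
# matrices for every parameter value. A transform matrix maps homogeneous
# points (row, col, 1); resampling uses inverse mapping (each output pixel
# pulls from the input).

tmatrix <- function(a, b, c, d, e, f) {
  matrix(c(a, b, c, d, e, f, 0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Elementary affine transform matrices
#'
#' 3x3 homogeneous matrices in the center-anchored convention: the offsets
#' are constructed so the image center `((h+1)/2, (w+1)/2)` is a fixed point
#' of rotation, shear and zoom. All four reduce to the identity at their
#' neutral parameters (theta = 0, tx = ty = 0, shear = 0, zx = zy = 1).
#'
#' @param theta Rotation angle in radians.
#' @param h,w Image height and width in pixels (>= 1).
#' @param tx,ty Shift in pixels along rows (height) and columns (width).
#' @param shear Shear intensity in radians, |shear| < pi/2.
#' @param zx,zy Zoom factors (> 0) along rows and columns.
#' @return A 3x3 numeric matrix with bottom row (0, 0, 1).
#' @export
rotation_matrix <- function(theta, h, w) {
  stopifnot_scalar_number(theta, "theta")
  stopifnot_scalar_number(h, "h"); stopifnot_scalar_number(w, "w")
  if (h < 1 || w < 1) stop("`h` and `w` must be >= 1", call. = FALSE)
  hc <- (h + 1) / 2; wc <- (w + 1) / 2
  tmatrix(cos(theta), -sin(theta), -cos(theta) * hc + sin(theta) * wc + hc,
          sin(theta),  cos(theta), -sin(theta) * hc - cos(theta) * wc + wc)
}

#' @rdname rotation_matrix
#' @export
shift_matrix <- function(tx, ty) {
  stopifnot_scalar_number(tx, "tx"); stopifnot_scalar_number(ty, "ty")
  tmatrix(1, 0, tx, 0, 1, ty)
}

#' @rdname rotation_matrix
#' @export
shear_matrix <- function(shear, h, w) {
  stopifnot_scalar_number(shear, "shear")
  stopifnot_scalar_number(h, "h"); stopifnot_scalar_number(w, "w")
  if (abs(shear) >= pi / 2) stop("|shear| must be < pi/2", call. = FALSE)
  wc <- (w + 1) / 2
  # linear part ((1, -sin s), (0, cos s)); offsets enforce the center fixed point
  tmatrix(1, -sin(shear), sin(shear) * wc,
          0,  cos(shear), (1 - cos(shear)) * wc)
}

#' @rdname rotation_matrix
#' @export
zoom_matrix <- function(zx, zy, h, w) {
  stopifnot_scalar_number(zx, "zx"); stopifnot_scalar_number(zy, "zy")
  stopifnot_scalar_number(h, "h"); stopifnot_scalar_number(w, "w")
  if (zx <= 0 || zy <= 0) stop("zoom factors must be > 0", call. = FALSE)
  hc <- (h + 1) / 2; wc <- (w + 1) / 2
  tmatrix(zx, 0, -zx * hc + hc,
          0, zy, -zy * wc + wc)
}

#' Augmentation configuration
#'
#' Ranges for the random affine draw plus resampling options. Defaults are
#' common augmentation practice for small photographic patches: rotation
#' within +/-40 degrees, shifts within +/-5 px, shear within +/-0.2 rad,
#' zoom in 0.8..1.2, horizontal flip with probability 0.5, bilinear
#' interpolation and edge-replicate fill.
#'
#' @param theta_range,shift_range,shear_range,zoom_range Closed intervals
#'   (length-2 numeric, radians / pixels / radians / scale factors).
#' @param flip_prob Horizontal-flip probability in `[0, 1]`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param fill `"edge"` (replicate border pixels) or `"constant"`.
#' @param fill_value Fill intensity when `fill = "constant"`.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(theta_range = c(-40, 40) * pi / 180,
                           shift_range = c(-5, 5),
                           shear_range = c(-0.2, 0.2),
                           zoom_range = c(0.8, 1.2),
                           flip_prob = 0.5,
                           interpolation = c("bilinear", "nearest"),
                           fill = c("edge", "constant"),
                           fill_value = 0) {
  interpolation <- match.arg(interpolation)
  fill <- match.arg(fill)
  for (nm in c("theta_range", "shift_range", "shear_range", "zoom_range")) {
    v <- get(nm)
    if (length(v) != 2L || !all(is.finite(v)) || v[1] > v[2]) {
      stop(sprintf("`%s` must be a non-empty closed interval", nm), call. = FALSE)
    }
  }
  if (flip_prob < 0 || flip_prob > 1) stop("`flip_prob` must be in [0, 1]", call. = FALSE)
  if (any(zoom_range <= 0)) stop("zoom factors must be > 0", call. = FALSE)
  structure(list(theta_range = theta_range, shift_range = shift_range,
                 shear_range = shear_range, zoom_range = zoom_range,
                 flip_prob = flip_prob, interpolation = interpolation,
                 fill = fill, fill_value = fill_value),
            class = "augment_config")
}

#' Apply an affine transform to a patch
#'
#' Resamples by inverse mapping: each output pixel pulls from the input at
#' the pre-image of its (row, col) center. Output values are clipped to
#' `[0, 255]` and rounded.
#'
#' @param image 50x50x3 (or any h x w x 3) numeric array.
#' @param m 3x3 transform matrix (must be invertible).
#' @param config An [augment_config()] controlling interpolation and fill.
#' @return Array of the same shape as `image`.
#' @export
apply_transform <- function(image, m, config = augment_config()) {
  d <- dim(image)
  if (length(d) != 3L) stop("`image` must be an h x w x channels array", call. = FALSE)
  if (abs(det(m)) < 1e-12) stop("singular transform matrix", call. = FALSE)
  h <- d[1]; w <- d[2]
  minv <- solve(m)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- minv[1, 1] * rows + minv[1, 2] * cols + minv[1, 3]  # source row coord
  v <- minv[2, 1] * rows + minv[2, 2] * cols + minv[2, 3]  # source col coord
  out <- array(0, d)
  if (config$interpolation == "nearest") {
    ui <- round(u); vi <- round(v)
    inside <- ui >= 1 & ui <= h & vi >= 1 & vi <= w
    ui <- clamp(ui, 1, h); vi <- clamp(vi, 1, w)
    idx <- cbind(as.vector(ui), as.vector(vi))
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch][idx]
      if (config$fill == "constant") plane[!inside] <- config$fill_value
      out[, , ch] <- matrix(plane, h, w)
    }
  } else {
    u0 <- floor(u); v0 <- floor(v)
    fu <- u - u0; fv <- v - v0
    inside <- u >= 1 & u <= h & v >= 1 & v <= w
    cu0 <- clamp(u0, 1, h); cu1 <- clamp(u0 + 1, 1, h)
    cv0 <- clamp(v0, 1, w); cv1 <- clamp(v0 + 1, 1, w)
    i00 <- cbind(as.vector(cu0), as.vector(cv0))
    i01 <- cbind(as.vector(cu0), as.vector(cv1))
    i10 <- cbind(as.vector(cu1), as.vector(cv0))
    i11 <- cbind(as.vector(cu1), as.vector(cv1))
    wfu <- as.vector(fu); wfv <- as.vector(fv)
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch]
      val <- plane[i00] * (1 - wfu) * (1 - wfv) + plane[i01] * (1 - wfu) * wfv +
             plane[i10] * wfu * (1 - wfv) + plane[i11] * wfu * wfv
      if (config$fill == "constant") val[!as.vector(inside)] <- config$fill_value
      out[, , ch] <- matrix(val, h, w)
    }
  }
  round(clamp(out, 0, 255))
}

#' Mirror a patch horizontally
#'
#' Reflects about the vertical center line (column `c` maps to `w + 1 - c`).
#' Exact involution: applying it twice returns the original patch.
#'
#' @param image h x w x channels array.
#' @return Flipped array.
#' @export
hflip <- function(image) {
  image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
}

#' Randomly augment one patch
#'
#' Draws affine parameters uniformly from the config ranges, composes
#' rotation %*% shift %*% shear %*% zoom into one matrix, applies it, then
#' flips horizontally with probability `flip_prob`. Deterministic for a given
#' seed (or for a given RNG state when `seed` is `NULL`).
#'
#' @param image h x w x 3 numeric array.
#' @param config An [augment_config()].
#' @param seed Optional integer seed.
#' @return Augmented array, same shape as the input.
#' @export
random_augment <- function(image, config = augment_config(), seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, random_augment(image, config)))
  d <- dim(image); h <- d[1]; w <- d[2]
  theta <- runif(1, config$theta_range[1], config$theta_range[2])
  tx <- runif(1, config$shift_range[1], config$shift_range[2])
  ty <- runif(1, config$shift_range[1], config$shift_range[2])
  sh <- runif(1, config$shear_range[1], config$shear_range[2])
  zx <- runif(1, config$zoom_range[1], config$zoom_range[2])
  zy <- runif(1, config$zoom_range[1], config$zoom_range[2])
  do_flip <- runif(1) < config$flip_prob
  m <- rotation_matrix(theta, h, w) %*% shift_matrix(tx, ty) %*%
       shear_matrix(sh, h, w) %*% zoom_matrix(zx, zy, h, w)
  out <- apply_transform(image, m, config)
  if (do_flip) out <- hflip(out)
  out
}

#' Enlarge a patch set to a target count per class by augmentation
#'
#' Originals are retained unchanged and listed first within each class;
#' additional patches are generated by augmenting the originals round-robin.
#' Classes already at or above the target are left unchanged.
#'
#' @param set A [patch_set()]; every class must be non-empty.
#' @param target_per_class Desired patches per class.
#' @param config An [augment_config()].
#' @param seed Integer seed for the augmentation draws.
#' @return A new `patch_set` (split tags dropped: augment before splitting).
#' @export
augment_to_target <- function(set, target_per_class, config = augment_config(),
                              seed = 0L) {
  stopifnot(inherits(set, "patch_set"))
  stopifnot_scalar_number(target_per_class, "target_per_class")
  counts <- tabulate(set$labels, nbins = length(set$class_names))
  if (any(counts == 0L)) {
    stop("every class must have at least one original patch", call. = FALSE)
  }
  with_seed(seed, {
    n_out <- sum(pmax(counts, target_per_class))
    x <- array(0, c(PATCH_SIDE, PATCH_SIDE, 3L, n_out))
    labels <- integer(n_out)
    i <- 0L
    for (ci in seq_along(set$class_names)) {
      idx <- which(set$labels == ci)
      for (j in idx) {              # originals first, untouched
        i <- i + 1L
        x[, , , i] <- set$x[, , , j]
        labels[i] <- ci
      }
      extra <- max(0L, as.integer(target_per_class) - length(idx))
      for (e in seq_len(extra)) {   # round-robin over the originals
        src <- idx[(e - 1L) %% length(idx) + 1L]
        i <- i + 1L
        x[, , , i] <- random_augment(set$x[, , , src], config)
        labels[i] <- ci
      }
    }
    patch_set(x, labels, set$class_names)
  })
}

#' Preprocessing specification
#'
#' Two schemes: `rescale_01` divides intensities by 255; `standardize`
#' subtracts a single global mean and divides by a single global standard
#' deviation (one scalar each, across all pixels and channels).
#'
#' @param mode `"rescale_01"` or `"standardize"`.
#' @param mean,std Global intensity mean and standard deviation (required for
#'   `standardize`; `std` must be > 0).
#' @return An object of class `preproc_spec`.
#' @export
preproc_spec <- function(mode = c("rescale_01", "standardize"),
                         mean = NULL, std = NULL) {
  mode <- match.arg(mode)
  if (mode == "standardize") {
    stopifnot_scalar_number(mean, "mean")
    stopifnot_scalar_number(std, "std")
    if (std <= 0) stop("`std` must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, mean = mean, std = std), class = "preproc_spec")
}

#' Fit a standardization spec from training pixels
#'
#' @param x Numeric array of raw 0..255 pixel data (any shape).
#' @return A `standardize` [preproc_spec()] with the global mean and sd of `x`.
#' @export
preproc_from_data <- function(x) {
  preproc_spec("standardize", mean = mean(x), std = stats::sd(as.vector(x)))
}

#' Apply a preprocessing spec to pixel data
#'
#' @param x Numeric array of raw 0..255 pixels (any shape).
#' @param spec A [preproc_spec()].
#' @return Real-valued array, same shape.
#' @export
preprocess <- function(x, spec) {
  stopifnot(inherits(spec, "preproc_spec"))
  switch(spec$mode,
    rescale_01 = x / 255,
    standardize = (x - spec$mean) / spec$std
  )
}
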