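# Whole-face diagnosis: tile, mask non-skin, classify skin tiles, aggregate.

#' Tile a face image into a sliding-window grid of 50x50 patches
#'
#' Non-overlapping stride-50 tiling, row-major, with recorded origins. If a
#' dimension is not a multiple of 50 the image is padded bottom/right with
#' black and the padded tiles are flagged so the skin detector forces them
#' to non-skin (a warning is raised).
#'
#' @param image h x w x 3 numeric array, values 0..255 (500x500 for the
#'   standard 10x10 grid).
#' @return An object of class `tile_grid`: list with `tiles`
#'   (50 x 50 x 3 x n array, row-major order), `rows`, `cols`, `origins`
#'   (data frame: `row`, `col`, 0-based pixel offsets `y0`, `x0`), and
#'   `padded` (logical per tile).
#' @export
tile_image <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`image` must be an h x w x 3 array", call. = FALSE)
  }
  side <- PATCH_SIDE
  h <- d[1]; w <- d[2]
  ph <- ceiling(h / side) * side
  pw <- ceiling(w / side) * side
  padded_img <- image
  if (ph != h || pw != w) {
    warning(sprintf("image %dx%d padded to %dx%d with black; padded tiles forced non-skin",
                    h, w, ph, pw), call. = FALSE)
    padded_img <- array(0, c(ph, pw, 3L))
    padded_img[seq_len(h), seq_len(w), ] <- image
  }
  rows <- ph / side; cols <- pw / side
  n <- rows * cols
  tiles <- array(0, c(side, side, 3L, n))
  origins <- data.frame(row = integer(n), col = integer(n),
                        y0 = integer(n), x0 = integer(n))
  padded <- logical(n)
  i <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      i <- i + 1L
      y0 <- (r - 1L) * side; x0 <- (cc - 1L) * side
      tiles[, , , i] <- padded_img[y0 + seq_len(side), x0 + seq_len(side), ]
      origins[i, ] <- list(r - 1L, cc - 1L, y0, x0)
      padded[i] <- (y0 + side > h) || (x0 + side > w)
    }
  }
  structure(list(tiles = tiles, rows = rows, cols = cols,
                 origins = origins, padded = padded,
                 image_dim = c(h, w)),
            class = "tile_grid")
}

#' Detect skin tiles with the binary classifier
#'
#' A tile is flagged skin when its skin-class probability is at least the
#' classifier's decision threshold. Padded tiles are always non-skin.
#'
#' @param grid A [tile_image()] grid.
#' @param binary A trained binary [acne_classifier()] whose first class is
#'   skin; its `threshold` must be set (see [calibrate_threshold()]) or
#'   `threshold` must be supplied.
#' @param threshold Optional override of the decision threshold.
#' @return An object of class `skin_mask`: list with `flags` (rows x cols
#'   logical matrix, TRUE = skin) and `skin_prob` (matching probabilities).
#' @export
detect_skin <- function(grid, binary, threshold = NULL) {
  stopifnot(inherits(grid, "tile_grid"), inherits(binary, "acne_classifier"))
  thr <- threshold %||% binary$threshold
  if (is.null(thr)) {
    stop("binary classifier has no decision threshold; calibrate or supply one",
         call. = FALSE)
  }
  probs <- predict(binary, grid$tiles)
  p_skin <- probs[, 1]
  flags <- p_skin >= thr & !grid$padded
  structure(list(
    flags = matrix(flags, grid$rows, grid$cols, byrow = TRUE),
    skin_prob = matrix(p_skin, grid$rows, grid$cols, byrow = TRUE)),
    class = "skin_mask")
}

#' Black out the non-skin tiles of an image
#'
#' @param image h x w x 3 array (tile-aligned with `mask`).
#' @param mask A [detect_skin()] mask.
#' @return The image with every non-skin tile set to 0 in all channels;
#'   skin tiles are untouched.
#' @export
mask_image <- function(image, mask) {
  stopifnot(inherits(mask, "skin_mask"))
  side <- PATCH_SIDE
  out <- image
  for (r in seq_len(nrow(mask$flags))) {
    for (cc in seq_len(ncol(mask$flags))) {
      if (!mask$flags[r, cc]) {
        ys <- (r - 1L) * side + seq_len(side)
        xs <- (cc - 1L) * side + seq_len(side)
        ys <- ys[ys <= dim(out)[1]]; xs <- xs[xs <= dim(out)[2]]
        out[ys, xs, ] <- 0
      }
    }
  }
  out
}

#' Classify the skin tiles with the seven-class classifier
#'
#' Only tiles flagged skin are scored; each result row is a normalized
#' 7-vector and the hard label is its argmax (ties to the lower class
#' index).
#'
#' @param grid A [tile_image()] grid.
#' @param mask A [detect_skin()] mask.
#' @param seven A trained seven-class [acne_classifier()].
#' @return List with `index` (tile indices, row-major), `probs`
#'   (n_skin x 7), and `labels` (argmax, 1-based into the seven-class
#'   vocabulary). Zero skin tiles give empty components.
#' @export
classify_tiles <- function(grid, mask, seven) {
  stopifnot(inherits(grid, "tile_grid"), inherits(mask, "skin_mask"))
  flags <- as.vector(t(mask$flags))      # back to row-major tile order
  idx <- which(flags)
  if (length(idx) == 0L) {
    return(list(index = integer(), probs = matrix(0, 0, 7), labels = integer()))
  }
  probs <- predict(seven, grid$tiles[, , , idx, drop = FALSE])
  list(index = idx, probs = probs,
       labels = max.col(probs, ties.method = "first"))
}

#' Per-class tile proportions over the skin area
#'
#' Component `c` is the fraction of skin tiles whose argmax class is `c`.
#'
#' @param tile_labels Integer labels (1-based) of the skin tiles.
#' @param k Number of classes (7).
#' @return Numeric `k`-vector summing to 1.
#' @export
tile_proportions <- function(tile_labels, k = 7L) {
  if (length(tile_labels) == 0L) {
    stop("no skin tiles: proportions undefined", call. = FALSE)
  }
  tabulate(tile_labels, nbins = k) / length(tile_labels)
}

#' Determine the symptom set from a proportion vector
#'
#' The normal-skin class (c3) is ignored; classes whose proportion reaches
#' `threshold` qualify; if more than `cap` qualify only the `cap` largest
#' are kept (boundary ties broken toward the lower class index). Applied to
#' the worked examples of the source protocol this reproduces all printed
#' class sets.
#'
#' @param p Numeric 7-vector of class proportions (c0..c6 order).
#' @param threshold Qualification threshold (default 0.10).
#' @param cap Maximum number of reported symptoms (default 3).
#' @return Character vector of qualifying class ids (subset of
#'   c0, c1, c2, c4, c5, c6), ordered by class index.
#' @export
determine_symptoms <- function(p, threshold = 0.10, cap = 3L) {
  if (length(p) != 7L || any(!is.finite(p)) || any(p < 0)) {
    stop("`p` must be a non-negative 7-vector", call. = FALSE)
  }
  classes <- acne_classes()
  cand <- setdiff(seq_len(7L), 4L)           # drop c3 (normal skin)
  cand <- cand[p[cand] >= threshold]
  if (length(cand) > cap) {
    # keep the `cap` largest; ties at the boundary favor the lower index
    ord <- cand[order(-p[cand], cand)]
    cand <- sort(ord[seq_len(cap)])
  }
  classes[cand]
}

#' End-to-end facial diagnosis
#'
#' Composes the pipeline: tile the image, mask non-skin tiles with the
#' binary classifier, classify the remaining tiles with the seven-class
#' classifier, aggregate argmax fractions, and determine the symptom set.
#'
#' @param image 500x500x3 (or any tile-aligned) numeric array, values
#'   0..255.
#' @param binary Trained binary [acne_classifier()] (threshold set).
#' @param seven Trained seven-class [acne_classifier()].
#' @param skin_threshold Optional override of the binary decision threshold.
#' @param symptom_threshold,symptom_cap Passed to [determine_symptoms()].
#' @return An object of class `diagnosis_report`: list with `proportions`
#'   (named 7-vector), `symptom_set`, `n_skin_tiles`, `n_masked_tiles`,
#'   `mask` (the [detect_skin()] result), `tiles` (per-skin-tile labels and
#'   probabilities), and `flagged_empty` (TRUE when no tile was skin).
#' @export
diagnose <- function(image, binary, seven, skin_threshold = NULL,
                     symptom_threshold = 0.10, symptom_cap = 3L) {
  grid <- tile_image(image)
  mask <- detect_skin(grid, binary, skin_threshold)
  res <- classify_tiles(grid, mask, seven)
  n_skin <- length(res$index)
  n_total <- grid$rows * grid$cols
  if (n_skin == 0L) {
    props <- setNames(rep(NA_real_, 7L), acne_classes())
    report <- list(proportions = props, symptom_set = character(),
                   n_skin_tiles = 0L, n_masked_tiles = n_total,
                   mask = mask, tiles = res, flagged_empty = TRUE)
    return(structure(report, class = "diagnosis_report"))
  }
  props <- setNames(tile_proportions(res$labels, 7L), acne_classes())
  structure(list(
    proportions = props,
    symptom_set = determine_symptoms(props, symptom_threshold, symptom_cap),
    n_skin_tiles = n_skin,
    n_masked_tiles = n_total - n_skin,
    mask = mask, tiles = res, flagged_empty = FALSE),
    class = "diagnosis_report")
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat("<diagnosis_report>\n")
  if (x$flagged_empty) {
    cat("  no skin tiles detected — empty report\n")
    return(invisible(x))
  }
  nm <- acne_class_names()
  cat(sprintf("  skin tiles: %d (masked: %d)\n", x$n_skin_tiles, x$n_masked_tiles))
  cat("  proportions:\n")
  for (i in seq_len(7)) {
    cat(sprintf("    %s %-11s %.2f\n", names(x$proportions)[i],
                nm[names(x$proportions)[i]], x$proportions[i]))
  }
  cat(sprintf("  symptoms: %s\n",
              if (length(x$symptom_set)) paste(x$symptom_set, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Write a diagnosis report to disk
#'
#' Writes `report.json` (proportions rounded to 2 decimals, symptom set,
#' counts), `mask.png` (the masked image with black non-skin blocks), and
#' `tiles.csv` (row, col, skin probability, argmax class per tile).
#'
#' @param report A [diagnose()] result.
#' @param image The diagnosed image (for the mask overlay).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_diagnosis <- function(report, image, dir) {
  stopifnot(inherits(report, "diagnosis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    proportions = as.list(round(report$proportions, 2)),
    symptom_set = report$symptom_set,
    n_skin_tiles = report$n_skin_tiles,
    n_masked_tiles = report$n_masked_tiles,
    flagged_empty = report$flagged_empty
  ), file.path(dir, "report.json"), auto_unbox = TRUE, pretty = TRUE)
  png::writePNG(mask_image(image, report$mask) / 255,
                file.path(dir, "mask.png"))
  nr <- nrow(report$mask$flags); nc <- ncol(report$mask$flags)
  df <- data.frame(row = rep(seq_len(nr) - 1L, each = nc),
                   col = rep(seq_len(nc) - 1L, times = nr),
                   skin_prob = as.vector(t(report$mask$skin_prob)),
                   class = NA_character_)
  if (length(report$tiles$index)) {
    df$class[report$tiles$index] <- acne_classes()[report$tiles$labels]
  }
  write.csv(df, file.path(dir, "tiles.csv"), row.names = FALSE)
  invisible(dir)
}
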