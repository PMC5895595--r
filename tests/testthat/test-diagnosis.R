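# Tiling, skin masking, tile classification, symptom determination.

stub_binary <- function(seed = 40) {
  ext <- tiny_extractor(seed)
  fdim <- ext$layers[[length(ext$layers)]]$output_shape
  acne_classifier(tiny_head(2, fdim, seed + 1), preproc_spec("rescale_01"),
                  skin_classes(), extractor = ext, threshold = 0.5)
}

stub_seven <- function(seed = 42) {
  ext <- tiny_extractor(seed)
  fdim <- ext$layers[[length(ext$layers)]]$output_shape
  acne_classifier(tiny_head(7, fdim, seed + 1), preproc_spec("rescale_01"),
                  acne_classes(), extractor = ext)
}

test_that("a 500x500 image tiles into a 10x10 grid that reassembles exactly", {
  face <- gen_face(matrix("c3", 10, 10), seed = 50)
  grid <- tile_image(face$image)
  expect_equal(grid$rows, 10); expect_equal(grid$cols, 10)
  expect_equal(dim(grid$tiles)[4], 100L)
  expect_identical(grid$tiles[, , , 1], face$image[1:50, 1:50, ])
  # row-major order: tile 12 is grid position (row 1, col 1) 0-based
  expect_equal(grid$origins[12, ], data.frame(row = 1L, col = 1L, y0 = 50L, x0 = 50L),
               ignore_attr = TRUE)
  rebuilt <- array(0, dim(face$image))
  for (i in seq_len(100)) {
    o <- grid$origins[i, ]
    rebuilt[o$y0 + 1:50, o$x0 + 1:50, ] <- grid$tiles[, , , i]
  }
  expect_identical(rebuilt, face$image)
  expect_false(any(grid$padded))
})

test_that("non-multiple dimensions pad with black and force padded tiles non-skin", {
  img <- array(120, c(70, 50, 3))
  expect_warning(grid <- tile_image(img), "padded")
  expect_equal(grid$rows, 2); expect_equal(grid$cols, 1)
  expect_true(grid$padded[2])
  expect_equal(unname(grid$tiles[30, 1, 1, 2]), 0)  # padded region is black
  mask <- detect_skin(grid, stub_binary(), threshold = 0)
  expect_false(mask$flags[2, 1])  # even threshold 0 cannot make a padded tile skin
})

test_that("threshold extremes flip every tile of the skin mask", {
  face <- gen_face(matrix("c3", 10, 10), seed = 51)
  grid <- tile_image(face$image)
  binary <- stub_binary()
  m0 <- detect_skin(grid, binary, threshold = 0)
  expect_true(all(m0$flags))
  m1 <- detect_skin(grid, binary, threshold = 1 + 1e-9)
  expect_false(any(m1$flags))
  expect_equal(dim(m0$flags), c(10L, 10L))
  # the stored probabilities line up with the flags
  thr <- 0.5
  mh <- detect_skin(grid, binary, threshold = thr)
  expect_identical(mh$flags, mh$skin_prob >= thr)
})

test_that("mask_image blacks out exactly the non-skin tiles", {
  face <- gen_face(matrix("c3", 10, 10), seed = 52)
  grid <- tile_image(face$image)
  binary <- stub_binary()
  all_skin <- detect_skin(grid, binary, threshold = 0)
  expect_identical(mask_image(face$image, all_skin), face$image)
  none <- detect_skin(grid, binary, threshold = 1 + 1e-9)
  expect_true(all(mask_image(face$image, none) == 0))
  # mixed mask: masked tiles exactly zero, others bit-equal
  mixed <- all_skin
  mixed$flags[3, 4] <- FALSE
  out <- mask_image(face$image, mixed)
  expect_true(all(out[101:150, 151:200, ] == 0))
  out[101:150, 151:200, ] <- face$image[101:150, 151:200, ]
  expect_identical(out, face$image)
})

test_that("classify_tiles scores only skin tiles with normalized rows", {
  face <- gen_face(matrix("c3", 10, 10), seed = 53)
  grid <- tile_image(face$image)
  binary <- stub_binary()
  mask <- detect_skin(grid, binary, threshold = 0)
  mask$flags[1, ] <- FALSE   # mask the first row of tiles
  res <- classify_tiles(grid, mask, stub_seven())
  expect_equal(length(res$index), 90L)
  expect_true(all(res$index > 10))
  expect_equal(rowSums(res$probs), rep(1, 90), tolerance = 1e-6)
  expect_true(all(res$labels %in% 1:7))
  # zero skin tiles -> empty result
  mask$flags[] <- FALSE
  res0 <- classify_tiles(grid, mask, stub_seven())
  expect_equal(length(res0$index), 0L)
})

test_that("tile proportions are argmax fractions that sum to one", {
  expect_equal(tile_proportions(rep(4L, 10)), c(0, 0, 0, 1, 0, 0, 0))
  p <- tile_proportions(rep(c(4L, 3L, 5L), times = c(60, 20, 20)))
  expect_equal(p, c(0, 0, 0.2, 0.6, 0.2, 0, 0))
  expect_equal(sum(p), 1)
  expect_error(tile_proportions(integer()), "undefined")
})

test_that("determine_symptoms applies the threshold, the cap and the c3 exclusion", {
  for (ex in symptom_examples()) {
    expect_identical(determine_symptoms(ex$p), ex$out)
  }
  # c3 never appears even when dominant; empty set when nothing qualifies
  expect_identical(determine_symptoms(c(0, 0, 0, 1, 0, 0, 0)), character())
  expect_identical(determine_symptoms(c(0.05, 0, 0, 0.8, 0.09, 0.03, 0.03)),
                   character())
  # boundary tie at the cap: equal proportions resolve to lower class indices
  tied <- c(0.2, 0.2, 0.2, 0, 0.2, 0.2, 0)
  expect_identical(determine_symptoms(tied), c("c0", "c1", "c2"))
  # cap is configurable
  expect_identical(determine_symptoms(tied, cap = 5),
                   c("c0", "c1", "c2", "c4", "c5"))
  expect_error(determine_symptoms(c(0.5, 0.5)), "7-vector")
})

test_that("symptom sets never exceed the cap and never contain c3", {
  set.seed(60)
  for (i in 1:200) {
    p <- runif(7); p <- p / sum(p)
    s <- determine_symptoms(p)
    expect_lte(length(s), 3)
    expect_false("c3" %in% s)
  }
})

test_that("diagnose composes the stages deterministically", {
  face <- gen_face(matrix("c3", 10, 10), seed = 54)
  binary <- stub_binary(); seven <- stub_seven()
  rep1 <- diagnose(face$image, binary, seven, skin_threshold = 0)
  expect_s3_class(rep1, "diagnosis_report")
  expect_equal(sum(rep1$proportions), 1)
  expect_equal(rep1$n_skin_tiles + rep1$n_masked_tiles, 100L)
  rep2 <- diagnose(face$image, binary, seven, skin_threshold = 0)
  expect_identical(rep1$proportions, rep2$proportions)
  # zero-skin images produce a flagged empty report
  rep0 <- diagnose(face$image, binary, seven, skin_threshold = 1 + 1e-9)
  expect_true(rep0$flagged_empty)
  expect_equal(rep0$n_skin_tiles, 0L)
  expect_identical(rep0$symptom_set, character())
})

test_that("diagnosis reports write JSON, mask PNG and per-tile CSV", {
  dir <- withr::local_tempdir()
  face <- gen_face(matrix("c3", 10, 10), seed = 55)
  rep1 <- diagnose(face$image, stub_binary(), stub_seven(), skin_threshold = 0)
  write_diagnosis(rep1, face$image, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$n_skin_tiles, 100L)
  expect_equal(length(js$proportions), 7L)
  tiles <- read.csv(file.path(dir, "tiles.csv"))
  expect_equal(nrow(tiles), 100L)
  expect_true(all(c("row", "col", "skin_prob", "class") %in% names(tiles)))
  expect_true(file.exists(file.path(dir, "mask.png")))
})
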