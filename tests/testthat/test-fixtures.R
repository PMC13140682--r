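test_that("synthetic generation honours counts, classes and determinism", {
  ds <- generate_synthetic_dataset(5, size = 128, seed = 0)
  expect_length(ds, 20)
  expect_equal(unname(table(dataset_labels(ds))), rep(5L, 4),
               ignore_attr = TRUE)
  for (im in ds) {
    expect_equal(dim(im$pixels), c(128, 128, 3))
    expect_true(min(im$pixels) >= 0 && max(im$pixels) <= 255)
  }
  ds2 <- generate_synthetic_dataset(5, size = 128, seed = 0)
  expect_identical(ds[[7]]$pixels, ds2[[7]]$pixels)
  ds3 <- generate_synthetic_dataset(2, size = 64, seed = 7)
  ds4 <- generate_synthetic_dataset(2, size = 64, seed = 7)
  expect_identical(lapply(ds3, `[[`, "pixels"), lapply(ds4, `[[`, "pixels"))
})

test_that("non-distinct hue centres are rejected", {
  sigs <- default_signatures()
  sigs$LGC$hue_center <- sigs$HGC$hue_center
  expect_error(generate_synthetic_dataset(2, signatures = sigs, seed = 1),
               "distinct hue")
})

test_that("classes are separable from flattened pixels by a boosted tree", {
  ds <- generate_synthetic_dataset(50, size = 128, seed = 1)
  X <- flatten_images(ds, resize = 32)
  y <- factor(attr(X, "labels"))
  folds <- endofuse:::stratified_folds(y, 10, seed = 5)
  correct <- 0L
  for (fi in 1:10) {
    tr <- folds != fi
    fit <- endofuse:::fit_gbt(X[tr, ], as.integer(y[tr]) - 1L, nlevels(y),
                              seed = fi)
    pred <- max.col(endofuse:::predict_gbt(fit, X[!tr, , drop = FALSE]))
    correct <- correct + sum(pred == as.integer(y[!tr]))
  }
  expect_gt(correct / length(y), 0.9)
})

test_that("stratified split reproduces the reference class table within one image", {
  labs <- c(rep("HGC", 469), rep("LGC", 647), rep("NST", 504), rep("NTL", 134))
  fake <- lapply(seq_along(labs), function(i) {
    labeled_image(array(0L, c(1, 1, 3)), labs[i], paste0("im", i))
  })
  sp <- stratified_split(fake, 0.1, 0.2, seed = 3)
  test_tab <- table(factor(dataset_labels(sp$test), levels = class_labels()))
  val_tab <- table(factor(dataset_labels(sp$validation), levels = class_labels()))
  train_tab <- table(factor(dataset_labels(sp$train), levels = class_labels()))
  expect_true(all(abs(as.integer(test_tab) - c(47, 65, 51, 13)) <= 1))
  expect_true(all(abs(as.integer(val_tab) - c(84, 117, 91, 24)) <= 1))
  expect_true(all(abs(as.integer(train_tab) - c(338, 465, 362, 97)) <= 1))
  # disjoint by source id
  ids <- list(dataset_ids(sp$train), dataset_ids(sp$validation),
              dataset_ids(sp$test))
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_length(intersect(ids[[1]], ids[[3]]), 0)
  expect_length(intersect(ids[[2]], ids[[3]]), 0)
  # determinism and seed sensitivity
  sp2 <- stratified_split(fake, 0.1, 0.2, seed = 3)
  expect_identical(dataset_ids(sp$test), dataset_ids(sp2$test))
  sp3 <- stratified_split(fake, 0.1, 0.2, seed = 4)
  expect_equal(length(sp3$test), length(sp$test))
  expect_false(identical(dataset_ids(sp$test), dataset_ids(sp3$test)))
})

test_that("split degenerate cases behave as contracted", {
  ds <- tiny_dataset()
  one_each <- ds[1:4]
  sp <- stratified_split(one_each, test_fraction = 0, val_fraction = 0.25,
                         seed = 1)
  expect_length(sp$test, 0)
  expect_length(c(sp$train, sp$validation), 4)
  expect_error(stratified_split(one_each, 0.25, 0.25, seed = 1),
               "degenerate")
})

test_that("set compositions satisfy the union arithmetic", {
  ds <- tiny_dataset()
  sp <- stratified_split(ds, 0.2, 0.25, seed = 2)
  d1 <- ds[1:3]
  sets <- dataset_compositions(sp, d1)
  expect_length(sets$D2, length(sets$Training) + length(sets$D1))
  expect_length(sets$D3, length(sets$Training) + length(sets$Validation))
  expect_length(sets$D4,
                length(sets$Training) + length(sets$Validation) + length(sets$D1))
})

test_that("PNG round trip is lossless and conversions warn", {
  dir <- withr::local_tempdir()
  px <- array(sample(0:255, 128 * 128 * 3, replace = TRUE), c(128, 128, 3))
  path <- file.path(dir, "x.png")
  write_image_png(px, path)
  back <- read_image_png(path)
  expect_identical(back$pixels, px)
  # grayscale becomes three equal channels
  gpath <- file.path(dir, "g.png")
  png::writePNG(matrix(runif(64), 8, 8), gpath)
  expect_warning(g <- read_image_png(gpath), "grayscale")
  expect_identical(g$pixels[, , 1], g$pixels[, , 2])
  expect_identical(g$pixels[, , 1], g$pixels[, , 3])
  # truncated file errors
  tpath <- file.path(dir, "t.png")
  raw_all <- readBin(path, "raw", file.size(path))
  writeBin(raw_all[1:30], tpath)
  expect_error(read_image_png(tpath), "cannot parse")
})

test_that("manifest round trip preserves labels, ids and pixels", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()[1:4]
  mp <- file.path(dir, "manifest.tsv")
  write_manifest(ds, file.path(dir, "img"), mp, split_name = "train")
  back <- read_manifest(mp)
  expect_identical(dataset_ids(back), dataset_ids(ds))
  expect_identical(dataset_labels(back), dataset_labels(ds))
  expect_identical(back[[2]]$pixels, ds[[2]]$pixels)
})
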