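test_that("preprocessing yields 128 x 128 in [0,1] for any input shape", {
  big <- array(255L, c(256, 256, 3))
  out <- preprocess_for_features(big)
  expect_equal(dim(out), c(128, 128, 3))
  expect_equal(max(abs(out - 1)), 0)
  odd <- array(sample(0:255, 64 * 100 * 3, TRUE), c(64, 100, 3))
  expect_equal(dim(preprocess_for_features(odd)), c(128, 128, 3))
  same <- array(sample(0:255, 128 * 128 * 3, TRUE), c(128, 128, 3))
  expect_equal(preprocess_for_features(same), same / 255)
  expect_error(preprocess_for_features(array(0, c(0, 4, 3))), "non-empty")
})

test_that("every group returns its contracted length, even on degenerate inputs", {
  sizes <- feature_groups()
  imgs <- list(
    synthetic = tiny_image(),
    constant = array(0.5, c(128, 128, 3)),
    noise = withr::with_seed(1, array(runif(128 * 128 * 3), c(128, 128, 3)))
  )
  for (nm in names(imgs)) {
    for (g in names(sizes)) {
      v <- extract_group(imgs[[nm]], g, seed = 1)
      expect_length(v, sizes[[g]])
      expect_true(all(is.finite(v)), label = paste(nm, g, "finite"))
    }
  }
  expect_error(extract_group(tiny_image(), "Gabor"), "unknown feature group")
})

test_that("concatenated vector has the full length and cumulative layout", {
  fv <- extract_all(tiny_image(), seed = 1)
  expect_length(fv$values, 34485)
  lay <- fv$layout
  expect_equal(lay$offset, cumsum(c(0, lay$length[-nrow(lay)])))
  expect_equal(lay$offset[lay$group == "Haralick"], 16384)
  expect_equal(lay$offset[lay$group == "ColorHistogram"], 16389)
  fv2 <- extract_all(tiny_image(), seed = 1)
  expect_identical(fv$values, fv2$values)
})

test_that("constant images give the degenerate statistics", {
  cimg <- array(0.25, c(128, 128, 3))
  expect_equal(extract_group(cimg, "Entropy"), 0)
  ps <- extract_group(cimg, "PixelStats")
  expect_equal(ps, c(0.25, 0.25, 0.25, 0, 0, 0))
  d <- extract_group(cimg, "DCT")
  expect_gt(abs(d[1]), 0)           # the (0,0) coefficient is the image sum
  expect_equal(max(abs(d[-1])), 0)  # all other coefficients vanish
})

test_that("DCT matches the direct double-loop definition on an 8 x 8 crop", {
  g <- to_gray_crop <- withr::with_seed(4, matrix(runif(64), 8, 8))
  direct <- matrix(0, 8, 8)
  for (u in 0:7) for (v in 0:7) {
    s <- 0
    for (m in 0:7) for (n in 0:7) {
      s <- s + g[m + 1, n + 1] *
        cos(pi * (2 * m + 1) * u / 16) * cos(pi * (2 * n + 1) * v / 16)
    }
    direct[u + 1, v + 1] <- s
  }
  expect_equal(endofuse:::dct2(g), direct, tolerance = 1e-10)
})

test_that("colour histogram counts sum to the pixel count per channel", {
  h <- extract_group(tiny_image(), "ColorHistogram")
  expect_equal(sum(h[1:256]), 128 * 128)
  expect_equal(sum(h[257:512]), 128 * 128)
  expect_equal(sum(h[513:768]), 128 * 128)
})

test_that("intensity statistics and colour histogram are flip invariant", {
  img <- tiny_image()
  flipped <- img[, 128:1, ]
  expect_equal(extract_group(img, "PixelStats"),
               extract_group(flipped, "PixelStats"))
  expect_equal(extract_group(img, "ColorHistogram"),
               extract_group(flipped, "ColorHistogram"))
})

test_that("LBP is the flattened per-pixel code map, not a histogram", {
  v <- extract_group(tiny_image(), "LBP")
  expect_length(v, 128 * 128)
  expect_true(all(v >= 0 & v <= 255))
  expect_true(all(v == round(v)))
  # a code map has spatial structure: many distinct codes, not 256 sums
  expect_gt(length(unique(v)), 50)
})

test_that("keypoint descriptors fall back to zero when nothing is detected", {
  flat <- array(0.7, c(128, 128, 3))
  expect_equal(extract_group(flat, "SIFT"), rep(0, 128))
  expect_equal(extract_group(flat, "ORB"), rep(0, 32))
})

test_that("dataset extraction stacks rows with labels and is deterministic", {
  ds <- tiny_dataset()[1:4]
  X <- extract_features(ds, seed = 3)
  expect_equal(dim(X), c(4, 34485))
  expect_identical(attr(X, "labels"), dataset_labels(ds))
  X2 <- extract_features(ds, seed = 3)
  expect_identical(unclass(X), unclass(X2))
})
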