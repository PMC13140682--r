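# A small trained model shared by the interpretation tests.
trained_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(12, {
        n <- 24
        y <- rep(0:3, each = 6)
        feats <- matrix(rnorm(n * 512, mean = rep(y, 512)), n)
        imgs <- array(0, c(32, 32, 3, n))
        for (i in 1:n) {
          imgs[, , , i] <- (y[i] + 1) / 5 +
            array(rnorm(32 * 32 * 3, 0, 0.05), c(32, 32, 3))
        }
      })
      td <- list(images = imgs, features = feats, labels = y)
      fit <- train_dual_branch(td, td, dual_branch_config(image_size = 32),
                               train_config(lr = 2e-3, epochs = 3,
                                            batch_size = 8, seed = 5))
      cache <<- list(model = fit$model, images = imgs, features = feats)
    }
    cache
  }
})

test_that("heatmaps are normalised, image-sized and deterministic", {
  toy <- trained_toy()
  img <- array(toy$images[, , , 1], c(32, 32, 3))
  hm <- gradcam(toy$model, img, features = toy$features[1, ])
  expect_s3_class(hm, "heatmap")
  expect_equal(dim(hm$values), c(32, 32))
  expect_gte(min(hm$values), 0)
  expect_lte(max(hm$values), 1)
  expect_true(all(hm$raw >= 0))  # rectified before normalisation
  hm2 <- gradcam(toy$model, img, features = toy$features[1, ],
                 target_class = hm$target_class)
  expect_identical(hm$values, hm2$values)
})

test_that("heatmaps depend on the target class", {
  toy <- trained_toy()
  img <- array(toy$images[, , , 1], c(32, 32, 3))
  h0 <- gradcam(toy$model, img, features = toy$features[1, ], target_class = 0)
  h3 <- gradcam(toy$model, img, features = toy$features[1, ], target_class = 3)
  expect_gt(max(abs(h0$values - h3$values)), 1e-6)
})

test_that("a class score cut off from the image yields the all-zero map", {
  m <- build_dual_branch(dual_branch_config(image_size = 32), seed = 7)
  # zero every fusion and head weight: gradients at the activation vanish
  for (g in c("fusion", "cnn_head")) {
    for (i in seq_along(m$groups[[g]])) {
      if (m$groups[[g]][[i]]$type == "linear") {
        m$groups[[g]][[i]]$W[] <- 0
        m$groups[[g]][[i]]$b[] <- 0
      }
    }
  }
  img <- withr::with_seed(1, array(runif(32 * 32 * 3), c(32, 32, 3)))
  hm <- gradcam(m, img, features = rep(0, 512), target_class = 2)
  expect_equal(max(hm$values), 0)
})

test_that("feature-only models refuse class-activation mapping", {
  cfg <- dual_branch_config(branches = "fnn_only",
                            fusion_dims = c(128, 256, 128, 4),
                            image_size = 32)
  m <- build_dual_branch(cfg, seed = 1)
  expect_error(gradcam(m, array(0, c(32, 32, 3))), "no convolutional branch")
})

test_that("overlay blending honours its endpoints and stays in range", {
  withr::with_seed(3, {
    px <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
    hm <- matrix(runif(64 * 64), 64, 64)
  })
  expect_identical(overlay(px, hm, alpha = 0), px)
  pure <- overlay(px, hm, alpha = 1)
  lut <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")))
  idx <- pmin(pmax(as.integer(round(hm * 255)) + 1L, 1L), 256L)
  expect_equal(pure[, , 1], matrix(lut[idx, 1], 64, 64), ignore_attr = TRUE)
  mid <- overlay(px, hm, alpha = 0.4)
  expect_true(all(mid >= 0 & mid <= 255))
  expect_error(overlay(px, hm[1:32, ]), "sizes differ")
})
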