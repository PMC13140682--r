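# A small shared config: study architecture widths, reduced image size.
db_cfg <- function(...) dual_branch_config(image_size = 32, ...)

test_that("built model matches the published branch widths exactly", {
  m <- build_dual_branch(db_cfg(), seed = 1)
  w <- model_layer_widths(m)
  expect_equal(w$fnn, c(512, 256, 128))
  expect_equal(w$cnn_head, c(1000, 512, 256))
  expect_equal(w$fusion, c(384, 256, 128, 4))
  expect_equal(w$dropout_after_hidden, rep(0.2, 6))
  # first FNN layer parameter count is forced by its dimensions
  lin1 <- m$groups$fnn[[1]]
  expect_equal(length(lin1$W) + length(lin1$b), 512 * 256 + 256)
  # final layer emits one raw score per class
  final <- m$groups$fusion[[length(m$groups$fusion)]]
  expect_equal(final$d_out, 4)
})

test_that("mismatched fusion widths fail construction with both widths named", {
  expect_error(dual_branch_config(fusion_dims = c(300, 256, 128, 4)),
               "FNN 128.*CNN 256")
})

test_that("forward pass is shaped, deterministic in eval and batch invariant", {
  m <- build_dual_branch(db_cfg(), seed = 2)
  withr::with_seed(1, {
    imgs <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
    feats <- matrix(rnorm(3 * 512), 3)
  })
  l1 <- model_forward(m, imgs, feats)$logits
  expect_equal(dim(l1), c(3, 4))
  l2 <- model_forward(m, imgs, feats)$logits
  expect_identical(l1, l2)
  single <- model_forward(m, imgs[, , , 1, drop = FALSE],
                          feats[1, , drop = FALSE])$logits
  expect_equal(as.vector(single), l1[1, ], tolerance = 1e-5)
  # training mode with dropout is stochastic
  t1 <- withr::with_seed(5, model_forward(m, imgs, feats, training = TRUE)$logits)
  t2 <- withr::with_seed(6, model_forward(m, imgs, feats, training = TRUE)$logits)
  expect_false(identical(t1, t2))
  # wrong feature width is a shape error
  expect_error(model_forward(m, imgs, feats[, 1:100]), "feature width")
})

test_that("probability modes normalise correctly and share their argmax", {
  m <- build_dual_branch(db_cfg(), seed = 3)
  withr::with_seed(2, {
    imgs <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
    feats <- matrix(rnorm(8 * 512), 8)
  })
  soft <- predict_dual_branch(m, imgs, feats, activation = "softmax")
  sig <- predict_dual_branch(m, imgs, feats, activation = "sigmoid")
  expect_equal(rowSums(soft$prob), rep(1, 8), tolerance = 1e-6)
  expect_identical(soft$labels, sig$labels)
  expect_identical(max.col(soft$prob), max.col(sig$prob))
})

test_that("an untrained model on balanced data predicts at chance level", {
  withr::with_seed(3, {
    imgs <- array(runif(32 * 32 * 3 * 40), c(32, 32, 3, 40))
    feats <- matrix(rnorm(40 * 512), 40)
    y <- rep(0:3, each = 10)
  })
  accs <- vapply(1:10, function(s) {
    m <- build_dual_branch(db_cfg(), seed = s)
    mean(predict_dual_branch(m, imgs, feats)$labels == y)
  }, numeric(1))
  expect_equal(mean(accs), 0.25, tolerance = 0.12)
})

test_that("training converges on separable data and keeps a full history", {
  withr::with_seed(4, {
    n <- 40
    y <- rep(0:3, each = 10)
    feats <- matrix(rnorm(n * 512, mean = rep(y, 512)), n)
    imgs <- array(0, c(32, 32, 3, n))
    for (i in 1:n) {
      imgs[, , , i] <- (y[i] + 1) / 5 + array(rnorm(32 * 32 * 3, 0, 0.05),
                                              c(32, 32, 3))
    }
  })
  td <- list(images = imgs, features = feats, labels = y)
  fit <- train_dual_branch(td, td, db_cfg(),
                           train_config(lr = 2e-3, epochs = 5,
                                        batch_size = 8, seed = 3))
  expect_equal(nrow(fit$history), 5)
  expect_named(fit$history,
               c("epoch", "train_loss", "train_acc", "train_f1",
                 "val_loss", "val_acc", "val_f1"))
  expect_gte(max(fit$history$val_f1), 0.95)
  # the checkpoint is the best-validation-F1 epoch
  pr <- predict_dual_branch(fit$model, imgs, feats)
  rep <- metric_report(y, y_pred = pr$labels, n_classes = 4)
  expect_gte(rep$F1, max(fit$history$val_f1) - 1e-9)
})

test_that("zero learning rate leaves every weight untouched", {
  withr::with_seed(6, {
    y <- rep(0:3, 2)
    feats <- matrix(rnorm(8 * 512), 8)
    imgs <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  })
  td <- list(images = imgs, features = feats, labels = y)
  fit <- train_dual_branch(td, td, db_cfg(),
                           train_config(lr = 0, epochs = 1, batch_size = 8,
                                        seed = 2))
  fresh <- build_dual_branch(db_cfg(), seed = 2)
  expect_equal(fit$final_model$groups$fnn[[1]]$W, fresh$groups$fnn[[1]]$W)
  expect_equal(fit$final_model$groups$backbone[[1]]$W,
               fresh$groups$backbone[[1]]$W)
})

test_that("a missing training class is rejected", {
  td <- list(images = array(0, c(32, 32, 3, 4)),
             features = matrix(0, 4, 512), labels = rep(0L, 4))
  expect_error(train_dual_branch(td, td, db_cfg(), train_config(epochs = 1)),
               "absent")
})

test_that("the model can memorise eight samples within 200 steps", {
  withr::with_seed(8, {
    y <- rep(0:3, 2)
    feats <- matrix(rnorm(8 * 512, mean = rep(y, 512)), 8)
    imgs <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  })
  td <- list(images = imgs, features = feats, labels = y)
  fit <- train_dual_branch(td, td, db_cfg(),
                           train_config(lr = 1e-2, epochs = 150,
                                        batch_size = 8, seed = 4))
  expect_lt(min(fit$history$train_loss), 0.05)
})

test_that("single-branch ablation variants build and run forward", {
  fnn_cfg <- dual_branch_config(branches = "fnn_only",
                                fusion_dims = c(128, 256, 128, 4),
                                image_size = 32)
  mf <- build_dual_branch(fnn_cfg, seed = 1)
  out <- model_forward(mf, features = matrix(rnorm(2 * 512), 2))$logits
  expect_equal(dim(out), c(2, 4))
  expect_length(mf$groups$backbone, 0)
  cnn_cfg <- dual_branch_config(branches = "cnn_only",
                                fusion_dims = c(256, 256, 128, 4),
                                image_size = 32)
  mc <- build_dual_branch(cnn_cfg, seed = 1)
  out <- model_forward(mc, images = array(runif(32 * 32 * 3), c(32, 32, 3, 1)))$logits
  expect_equal(dim(out), c(1, 4))
  expect_length(mc$groups$fnn, 0)
})
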