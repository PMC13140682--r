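test_that("Yeo-Johnson closed form matches its defining cases", {
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(yeo_johnson(x, 1), x)           # identity parameter
  expect_equal(yeo_johnson(0, -1.7), 0)        # fixed point for any lambda
  expect_equal(yeo_johnson(0, 2), 0)
  expect_equal(yeo_johnson(3, 0), log(4))
  expect_equal(yeo_johnson(-3, 2), -log(4))
  expect_equal(yeo_johnson(3, 0.5), ((4)^0.5 - 1) / 0.5)
})

test_that("Yeo-Johnson is strictly increasing in x for fixed lambda", {
  withr::with_seed(8, {
    for (lam in c(-1.5, 0, 0.7, 1, 2, 2.8)) {
      x <- sort(runif(200, -10, 10))
      y <- yeo_johnson(x, lam)
      expect_true(all(diff(y) > 0), label = paste("lambda", lam))
    }
  })
})

test_that("fitted lambdas gaussianise skewed columns and survive round trips", {
  X <- withr::with_seed(2, cbind(rexp(300), rnorm(300), rep(1, 300)))
  expect_message(par <- fit_yeo_johnson(X), "constant column")
  expect_length(par$lambda, 3)
  expect_equal(par$lambda[3], 1)  # constant column left as identity
  Xt <- apply_yeo_johnson(X, par)
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  expect_lt(abs(skew(Xt[, 1])), abs(skew(X[, 1])))
  # held-out application uses the same closed form
  expect_equal(Xt[5, 1], yeo_johnson(X[5, 1], par$lambda[1]))
})

test_that("the CV harness ranks a separable table near-perfectly and is seeded", {
  tab <- separable_table(n_per_class = 15, p = 8, sep = 4, seed = 3)
  models <- c("gbt", "lda", "dt", "knn")
  rep1 <- cross_validate_models(tab$X, tab$y, models = models, k = 5, seed = 9)
  expect_equal(nrow(rep1), length(models))
  expect_gte(rep1$F1_mean[1], 0.95)
  expect_true(all(rep1$SPEC_mean >= 0 & rep1$SPEC_mean <= 1))
  rep2 <- cross_validate_models(tab$X, tab$y, models = models, k = 5, seed = 9)
  expect_identical(rep1, rep2)
  expect_error(cross_validate_models(tab$X, tab$y, models = "mystery", k = 5),
               "models")
})

test_that("every roster model fits, predicts probabilities and scores", {
  tab <- separable_table(n_per_class = 12, p = 6, sep = 4, seed = 5)
  for (nm in model_roster()) {
    fit <- fit_roster_model(nm, tab$X, tab$y, seed = 2)
    prob <- predict_roster_model(fit, tab$X)
    expect_equal(dim(prob), c(nrow(tab$X), 4), label = nm)
    expect_true(all(prob >= -1e-9 & prob <= 1 + 1e-9), label = nm)
    acc <- mean(class_labels()[max.col(prob)] == tab$y)
    expect_gt(acc, 0.5)
  }
})

test_that("infeasible stratification is rejected", {
  tab <- separable_table(n_per_class = 1, p = 4, seed = 1)
  expect_error(cross_validate_models(tab$X, tab$y, models = "gbt", k = 2),
               "infeasible")
})

test_that("RFE identity case returns all columns without any fits", {
  tab <- separable_table(n_per_class = 8, p = 5, seed = 2)
  res <- rfe_select(tab$X, tab$y, target_k = 5, seed = 1)
  expect_equal(res$selected, 1:5)
  expect_equal(res$n_fits, 0L)
  expect_length(res$eliminated_order, 0)
})

test_that("RFE keeps the single label-determining column", {
  # column 3 alone determines the label; the rest is noise
  withr::with_seed(6, {
    y <- rep(class_labels(), each = 25)
    X <- matrix(rnorm(100 * 5), 100, 5)
    X[, 3] <- as.integer(factor(y)) + rnorm(100, 0, 0.05)
  })
  # oracle: exhaustive single-feature training accuracy
  single_acc <- vapply(1:5, function(j) {
    fit <- endofuse:::fit_gbt(X[, j, drop = FALSE],
                              as.integer(factor(y)) - 1L, 4, seed = 1)
    mean(max.col(endofuse:::predict_gbt(fit, X[, j, drop = FALSE])) ==
           as.integer(factor(y)))
  }, numeric(1))
  expect_equal(which.max(single_acc), 3L)
  res <- rfe_select(X, y, target_k = 1, seed = 4)
  expect_equal(res$selected, 3L)
})

test_that("RFE rejects wrappers without importances and accepts forest wrappers", {
  tab <- separable_table(n_per_class = 8, p = 10, sep = 4, seed = 9)
  expect_error(rfe_select(tab$X, tab$y, target_k = 2, wrapper = "knn"),
               "does not expose feature importances")
  res <- rfe_select(tab$X, tab$y, target_k = 4, wrapper = "rf", seed = 2)
  expect_length(res$selected, 4)
  expect_equal(res$wrapper, "rf")
})

test_that("RFE elimination yields strictly nested subsets", {
  tab <- separable_table(n_per_class = 10, p = 30, sep = 2, seed = 7)
  res <- rfe_select(tab$X, tab$y, target_k = 4, seed = 3)
  expect_length(res$selected, 4)
  expect_equal(sort(c(res$selected, res$eliminated_order)), 1:30)
  expect_false(anyDuplicated(res$eliminated_order) > 0)
  # reconstruct the subset sequence from the elimination log: each prefix
  # removal gives S_{t+1} strictly contained in S_t
  surv <- 1:30
  for (e in res$eliminated_order) {
    nxt <- setdiff(surv, e)
    expect_length(nxt, length(surv) - 1)
    expect_true(all(nxt %in% surv))
    surv <- nxt
  }
  expect_setequal(surv, res$selected)
})
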