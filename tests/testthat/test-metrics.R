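test_that("confusion counts match the hand-derived binary example", {
  cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(cc$TP, c(1, 2))
  expect_equal(cc$FN, c(1, 0))
  expect_equal(cc$FP, c(0, 1))
  expect_equal(cc$TN, c(2, 1))
  expect_equal(unname(cc$TP + cc$FP + cc$TN + cc$FN), c(4, 4))
  expect_equal(sum(cc$TP), sum(diag(cc$matrix)))
  expect_error(confusion_counts(integer(0), integer(0), 2), "empty")
  expect_error(confusion_counts(c(0, 5), c(0, 1), 2), "out of range")
})

test_that("macro metrics evaluate the hand example and the identity cases", {
  mm <- macro_metrics(confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 1), 2))
  expect_equal(mm$REC, 0.75)
  expect_equal(mm$SPEC, 0.75)
  expect_equal(mm$PREC, 5 / 6, tolerance = 1e-12)
  expect_equal(mm$F1, (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  expect_equal(mm$MCC, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(mm$ACC, 0.75)
  # perfect predictions give 1 everywhere
  perfect <- macro_metrics(confusion_counts(c(0, 1, 2, 3), c(0, 1, 2, 3), 4))
  for (m in c("REC", "SPEC", "ACC", "PREC", "F1", "MCC")) {
    expect_equal(perfect[[m]], 1)
  }
  # collapsing onto one class over balanced truth: macro recall 1/C
  y <- rep(0:3, each = 5)
  collapsed <- macro_metrics(confusion_counts(y, rep(0L, 20), 4))
  expect_equal(collapsed$REC, 0.25)
})

test_that("the as-reported accuracy mode returns macro recall", {
  cc <- confusion_counts(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 2, 2, 2), 3)
  asis <- macro_metrics(cc)
  rep_mode <- macro_metrics(cc, mode = "as-reported")
  expect_equal(rep_mode$ACC, asis$REC)
  expect_false(isTRUE(all.equal(asis$ACC, asis$REC)))
})

test_that("macro metrics agree with the literal formula transcription", {
  withr::with_seed(123, {
    worst <- 0
    for (i in 1:1000) {
      cc <- random_counts(C = sample(2:5, 1))
      got <- macro_metrics(cc)
      want <- oracle_macro_metrics(cc$TP, cc$FP, cc$TN, cc$FN)
      for (m in names(want)) {
        worst <- max(worst, abs(got[[m]] - want[[m]]))
      }
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("binary MCC hits +1 and -1 at perfect and anti-perfect prediction", {
  y <- rep(c(0L, 1L), 10)
  expect_equal(macro_metrics(confusion_counts(y, y, 2))$MCC, 1)
  expect_equal(macro_metrics(confusion_counts(y, 1L - y, 2))$MCC, -1)
})

test_that("binary one-vs-rest macro recall equals macro specificity", {
  withr::with_seed(42, {
    for (i in 1:20) {
      y <- sample(0:1, 30, replace = TRUE)
      p <- sample(0:1, 30, replace = TRUE)
      mm <- macro_metrics(confusion_counts(y, p, 2))
      expect_equal(mm$REC, mm$SPEC)
    }
  })
})

test_that("ROC/PR areas behave at the perfect, random and reversed extremes", {
  # one-hot truth scores: perfect ranking
  y <- rep(0:3, each = 5)
  onehot <- diag(4)[y + 1, ]
  tc <- threshold_curves(y, onehot)
  expect_equal(tc$AUC, 1)
  expect_equal(tc$AUPR, 1)
  # label-independent scores: AUC near 1/2
  withr::with_seed(7, {
    n <- 10000
    y <- sample(0:3, n, replace = TRUE)
    sc <- matrix(runif(4 * n), n, 4)
    expect_equal(threshold_curves(y, sc)$AUC, 0.5, tolerance = 0.02)
  })
  # reversing scores maps AUC to its complement
  withr::with_seed(9, {
    y <- sample(0:1, 200, replace = TRUE)
    sc <- cbind(runif(200), runif(200))
    a <- threshold_curves(y, sc)$auc
    b <- threshold_curves(y, -sc)$auc
    expect_equal(a, 1 - b, tolerance = 1e-10)
  })
})

test_that("per-class AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    y <- sample(0:2, 120, replace = TRUE)
    sc <- matrix(rnorm(3 * 120), 120, 3) + 0.8 * diag(3)[y + 1, ]
    tc <- threshold_curves(y, sc)
    for (ci in 1:3) {
      ref <- pROC::auc(pROC::roc(as.integer(y == ci - 1), sc[, ci],
                                 quiet = TRUE, direction = "<"))
      expect_equal(tc$auc[ci], as.numeric(ref), tolerance = 1e-10)
    }
  })
})

test_that("absent classes are excluded from the macro mean with a warning", {
  y <- rep(0L, 10)
  sc <- cbind(runif(10), runif(10))
  expect_warning(tc <- threshold_curves(y, sc), "absent")
  expect_true(is.na(tc$auc[2]))
  expect_false(is.na(tc$AUC))
})

test_that("metric_report combines counts, curves and argmax predictions", {
  withr::with_seed(5, {
    y <- sample(0:3, 60, replace = TRUE)
    sc <- matrix(rnorm(240), 60, 4) + 2 * diag(4)[y + 1, ]
    rep <- metric_report(y, scores = sc)
    expect_s3_class(rep, "metric_report")
    expect_equal(rep$counts$n, 60)
    pred <- max.col(sc) - 1L
    expect_equal(sum(diag(rep$counts$matrix)), sum(pred == y))
    expect_true(rep$AUC > 0.9)
    expect_equal(nrow(rep$curves$macro_roc), 1000)
  })
})
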