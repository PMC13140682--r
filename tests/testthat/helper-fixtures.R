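# Shared fixtures, built once per test run.

# Small synthetic dataset (6 per class, 128 px) reused across files.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_dataset(6, size = 128, seed = 11)
    }
    cache
  }
})

# One preprocessed synthetic frame.
tiny_image <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocess_for_features(tiny_dataset()[[1]])
    cache
  }
})

# A linearly separable Gaussian-blob feature table: class means spread far
# apart relative to noise.
separable_table <- function(n_per_class = 20, p = 10, sep = 4, seed = 1,
                            classes = class_labels()) {
  withr::with_seed(seed, {
    k <- length(classes)
    centers <- matrix(rnorm(k * p), k, p) * sep
    X <- do.call(rbind, lapply(seq_len(k), function(ci) {
      matrix(rnorm(n_per_class * p), n_per_class, p) +
        matrix(centers[ci, ], n_per_class, p, byrow = TRUE)
    }))
    y <- rep(classes, each = n_per_class)
    list(X = X, y = y)
  })
}

# Literal term-by-term transcription of the six macro metric formulas,
# written independently of macro_metrics() as the fidelity oracle.
oracle_macro_metrics <- function(tp, fp, tn, fn) {
  C <- length(tp)
  rec <- spec <- acc <- prec <- f1 <- mcc <- numeric(C)
  for (i in seq_len(C)) {
    rec[i] <- if (tp[i] + fn[i] > 0) tp[i] / (tp[i] + fn[i]) else 0
    spec[i] <- if (tn[i] + fp[i] > 0) tn[i] / (tn[i] + fp[i]) else 0
    acc[i] <- if (tp[i] + tn[i] + fp[i] + fn[i] > 0) {
      (tp[i] + tn[i]) / (tp[i] + tn[i] + fp[i] + fn[i])
    } else 0
    prec[i] <- if (tp[i] + fp[i] > 0) tp[i] / (tp[i] + fp[i]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
    den <- sqrt(tp[i] + fp[i]) * sqrt(tp[i] + fn[i]) *
      sqrt(tn[i] + fp[i]) * sqrt(tn[i] + fn[i])
    mcc[i] <- if (den > 0) (tp[i] * tn[i] - fp[i] * fn[i]) / den else 0
  }
  list(REC = sum(rec) / C, SPEC = sum(spec) / C, ACC = sum(acc) / C,
       PREC = sum(prec) / C, F1 = sum(f1) / C, MCC = sum(mcc) / C)
}

# Random per-class one-vs-rest count table consistent with a confusion
# matrix over n samples and C classes.
random_counts <- function(C = 4, n_max = 40) {
  n <- sample(C:n_max, 1)
  y_true <- sample(0:(C - 1), n, replace = TRUE)
  y_pred <- sample(0:(C - 1), n, replace = TRUE)
  confusion_counts(y_true, y_pred, C)
}
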