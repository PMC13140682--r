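# Macro-averaged multi-class metrics. Every metric is computed per class in
# one-vs-rest form and averaged with equal class weight: recall,
# specificity, accuracy, precision, F1, Matthews correlation, and the areas
# under the ROC and precision-recall curves.

#' One-vs-rest confusion counts
#'
#' @param y_true integer labels in `0 .. n_classes - 1`
#' @param y_pred predicted labels, same coding and length
#' @param n_classes number of classes C
#' @return a `confusion_counts` list: per-class `TP`, `FP`, `TN`, `FN`
#'   vectors, the C x C confusion `matrix` (rows = truth) and `n`
#' @export
confusion_counts <- function(y_true, y_pred, n_classes) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true < 0 | y_true >= n_classes | y_pred < 0 | y_pred >= n_classes)) {
    stop("labels out of range 0 .. C-1")
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- length(y_true) - tp - fn - fp
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, matrix = cm,
                 n = length(y_true), C = n_classes),
            class = "confusion_counts")
}

# Per-class ratio with the zero-denominator-to-zero convention.
safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Macro threshold metrics from confusion counts
#'
#' Macro recall, specificity, accuracy, precision, F1 and MCC, each the
#' unweighted mean of per-class one-vs-rest values. Accuracy averages the
#' per-class one-vs-rest accuracies `(TP + TN) / n` by default
#' (`mode = "per-class"`); `mode = "as-reported"` instead reports macro
#' recall under the ACC heading, the convention many published comparison
#' tables follow. Per-class terms with a zero denominator contribute 0.
#'
#' @param counts a `confusion_counts` object
#' @param mode accuracy convention, `"per-class"` or `"as-reported"`
#' @return list with the six macro metrics and a `per_class` data frame
#' @export
macro_metrics <- function(counts, mode = c("per-class", "as-reported")) {
  mode <- match.arg(mode)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  rec <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  list(REC = mean(rec), SPEC = mean(spec),
       ACC = if (mode == "as-reported") mean(rec) else mean(acc),
       PREC = mean(prec), F1 = mean(f1), MCC = mean(mcc),
       per_class = data.frame(class = seq_along(tp) - 1L, REC = rec,
                              SPEC = spec, ACC = acc, PREC = prec,
                              F1 = f1, MCC = mcc))
}

# Single-class ROC curve (one-vs-rest); returns fpr/tpr stepping through
# unique score thresholds, ties grouped.
roc_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  dup <- rev(duplicated(rev(score)))  # TRUE if next score identical
  tps <- cumsum(truth)[!dup]
  fps <- cumsum(!truth)[!dup]
  P <- sum(truth); N <- length(truth) - P
  list(fpr = c(0, fps / max(N, 1)), tpr = c(0, tps / max(P, 1)),
       tps = c(0, tps), fps = c(0, fps), P = P, N = N)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head_(y) + tail_(y)) / 2)
}
head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Per-class and macro ROC / precision-recall curves
#'
#' One-vs-rest curves per class: AUC by the trapezoidal rule, AUPR by
#' stepwise (right-continuous) interpolation of precision over recall.
#' Macro curves average the per-class curves on a shared 1000-point grid
#' (linear interpolation for ROC, stepwise-constant for PR). A class
#' absent from `y_true` is excluded from the macro means with a warning.
#'
#' @param y_true integer labels in `0 .. C - 1`
#' @param scores numeric matrix of per-class scores, one column per class
#' @param grid_points number of grid points for the macro curves
#' @return list: `auc` / `aupr` per class (NA when undefined), `AUC` /
#'   `AUPR` macro means, `roc` / `pr` per-class curves, and
#'   `macro_roc` / `macro_pr` interpolated curves
#' @export
threshold_curves <- function(y_true, scores, grid_points = 1000) {
  scores <- as.matrix(scores)
  C <- ncol(scores)
  stopifnot(length(y_true) == nrow(scores))
  auc <- rep(NA_real_, C)
  aupr <- rep(NA_real_, C)
  rocs <- vector("list", C)
  prs <- vector("list", C)
  grid <- seq(0, 1, length.out = grid_points)
  roc_interp <- matrix(NA_real_, grid_points, C)
  pr_interp <- matrix(NA_real_, grid_points, C)
  for (ci in seq_len(C)) {
    truth <- y_true == (ci - 1L)
    if (!any(truth)) next
    rp <- roc_points(truth, scores[, ci])
    auc[ci] <- trapezoid(rp$fpr, rp$tpr)
    rocs[[ci]] <- data.frame(fpr = rp$fpr, tpr = rp$tpr)
    # PR: precision at each threshold step; AP-style step integration
    prec <- safe_div(rp$tps, rp$tps + rp$fps)
    recl <- rp$tpr
    prec[1] <- if (length(prec) > 1) prec[2] else 1
    aupr[ci] <- sum(diff(recl) * tail_(prec))
    prs[[ci]] <- data.frame(recall = recl, precision = prec)
    roc_interp[, ci] <- stats::approx(rp$fpr, rp$tpr, xout = grid,
                                      ties = "ordered", rule = 2)$y
    pr_interp[, ci] <- stats::approx(recl, prec, xout = grid,
                                     method = "constant", f = 1,
                                     ties = "ordered", rule = 2)$y
  }
  if (anyNA(auc)) {
    warning("class(es) absent from y_true excluded from macro AUC/AUPR: ",
            paste(which(is.na(auc)) - 1L, collapse = ", "))
  }
  list(auc = auc, aupr = aupr,
       AUC = mean(auc, na.rm = TRUE), AUPR = mean(aupr, na.rm = TRUE),
       roc = rocs, pr = prs,
       macro_roc = data.frame(fpr = grid,
                              tpr = rowMeans(roc_interp, na.rm = TRUE)),
       macro_pr = data.frame(recall = grid,
                             precision = rowMeans(pr_interp, na.rm = TRUE)))
}

#' Full metric report
#'
#' Computes the six threshold metrics (and, when per-class scores are
#' given, macro AUC and AUPR) for a prediction set. When `y_pred` is
#' missing it is taken as the per-row argmax of `scores`.
#'
#' @param y_true integer labels in `0 .. C - 1`
#' @param y_pred optional predicted labels, same coding
#' @param scores optional per-class score matrix
#' @param n_classes number of classes (inferred from `scores` if absent)
#' @param mode accuracy convention passed to [macro_metrics()]
#' @return a `metric_report` list with REC, SPEC, ACC, PREC, F1, MCC, AUC,
#'   AUPR, `per_class`, `counts` and `curves`
#' @export
metric_report <- function(y_true, y_pred = NULL, scores = NULL,
                          n_classes = NULL, mode = "per-class") {
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(scores)) ncol(scores) else max(y_true, y_pred) + 1L
  }
  if (is.null(y_pred)) {
    stopifnot(!is.null(scores))
    y_pred <- max.col(as.matrix(scores), ties.method = "first") - 1L
  }
  counts <- confusion_counts(y_true, y_pred, n_classes)
  mm <- macro_metrics(counts, mode = mode)
  curves <- NULL
  if (!is.null(scores)) {
    curves <- threshold_curves(y_true, scores)
    mm$AUC <- curves$AUC
    mm$AUPR <- curves$AUPR
  } else {
    mm$AUC <- NA_real_
    mm$AUPR <- NA_real_
  }
  structure(c(mm, list(counts = counts, curves = curves)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  vals <- unlist(x[c("REC", "SPEC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")])
  cat("Macro metrics (", x$counts$n, " samples, ", x$counts$C, " classes)\n",
      sep = "")
  print(round(vals, 4))
  invisible(x)
}
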