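# Feature normalisation and selection: per-column Yeo-Johnson power
# transform fitted by maximum likelihood, a 12-model stratified
# cross-validation harness for wrapper selection, and recursive feature
# elimination (RFE) under a gradient-boosted wrapper.

#' Yeo-Johnson power transform (closed form)
#'
#' For `x >= 0`: `((x + 1)^lambda - 1) / lambda` (`lambda != 0`) or
#' `log(x + 1)` (`lambda == 0`); for `x < 0`:
#' `-(((-x + 1)^(2 - lambda)) - 1) / (2 - lambda)` (`lambda != 2`) or
#' `-log(-x + 1)` (`lambda == 2`). Strictly increasing in `x` for any
#' fixed `lambda`; `x = 0` is a fixed point and `lambda = 1` the identity.
#'
#' @param x numeric vector
#' @param lambda scalar transform parameter
#' @return transformed vector of the same length
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- -(((-x[!pos] + 1)^(2 - lambda)) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

# Profile log-likelihood of lambda for one or more columns; X is n x p,
# returns length-p vector.
yj_loglik <- function(X, lambda) {
  n <- nrow(X)
  psi <- apply(X, 2, yeo_johnson, lambda = lambda)
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = n)
  mu <- colMeans(psi)
  s2 <- colMeans(psi^2) - mu^2
  jac <- colSums(sign(X) * log1p(abs(X)))
  -n / 2 * log(pmax(s2, 1e-300)) + (lambda - 1) * jac
}

#' Fit per-column Yeo-Johnson parameters by maximum likelihood
#'
#' A lambda grid search with parabolic refinement, per feature column.
#' Constant columns get `lambda = 1` (identity) with a message. Fit on
#' training rows only; apply the fitted parameters to held-out rows with
#' [apply_yeo_johnson()].
#'
#' @param X numeric matrix (rows = samples)
#' @param grid candidate lambda values
#' @param block columns processed per block (memory control)
#' @return a `yj_params` list with `lambda` per column
#' @export
fit_yeo_johnson <- function(X, grid = seq(-2, 3, by = 0.1), block = 4000L) {
  p <- ncol(X)
  lambda <- rep(1, p)
  const <- matrixStats_colSds(X) < 1e-12
  if (any(const)) {
    message(sum(const), " constant column(s): lambda fixed to 1 (identity)")
  }
  todo <- which(!const)
  for (start in seq(1, length(todo), by = block)) {
    cols <- todo[start:min(start + block - 1L, length(todo))]
    Xb <- X[, cols, drop = FALSE]
    ll <- vapply(grid, function(lam) yj_loglik(Xb, lam),
                 numeric(length(cols)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = length(cols))
    best <- max.col(ll, ties.method = "first")
    lam_hat <- grid[best]
    # parabolic refinement where the optimum is interior to the grid
    interior <- best > 1 & best < length(grid)
    if (any(interior)) {
      i <- which(interior)
      b <- best[i]
      y0 <- ll[cbind(i, b - 1L)]; y1 <- ll[cbind(i, b)]; y2 <- ll[cbind(i, b + 1L)]
      denom <- y0 - 2 * y1 + y2
      shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
      step <- grid[2] - grid[1]
      lam_hat[i] <- grid[b] + pmin(pmax(shift, -1), 1) * step
    }
    lambda[cols] <- lam_hat
  }
  structure(list(lambda = lambda), class = "yj_params")
}

# colSds without a matrixStats dependency.
matrixStats_colSds <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0) * n / (n - 1))
}

#' Apply fitted Yeo-Johnson parameters to a feature table
#'
#' @param X numeric matrix with the same column count the parameters were
#'   fitted on
#' @param params a `yj_params` object from [fit_yeo_johnson()]
#' @return transformed matrix of the same shape
#' @export
apply_yeo_johnson <- function(X, params) {
  stopifnot(inherits(params, "yj_params"), ncol(X) == length(params$lambda))
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- yeo_johnson(X[, j], params$lambda[j])
  }
  out
}

## ---- Model roster ----------------------------------------------------

#' The twelve-model roster of the cross-validation harness
#'
#' Classical classifiers spanning instance-based, tree, linear, kernel,
#' neural and boosted families. Each entry can produce per-class
#' probability scores.
#'
#' @return character vector of roster model names
#' @export
model_roster <- function() {
  c("knn", "rf", "extra_trees", "dt", "lr", "nb", "lda", "mlp", "svm",
    "glmnet", "gbt", "linear_boost")
}

# Fit one roster model; X numeric matrix, y factor. Returns an object for
# predict_roster_model().
fit_roster_model <- function(name, X, y, seed = 1) {
  y <- droplevels(as.factor(y))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- with_seed(derive_seed(seed, "fit", name), switch(name,
    knn = list(X = X, y = y, k = 5L),
    rf = ranger::ranger(x = X, y = y, probability = TRUE, num.trees = 200,
                        seed = derive_seed(seed, "ranger"), num.threads = 1),
    extra_trees = ranger::ranger(x = X, y = y, probability = TRUE,
                                 num.trees = 200, splitrule = "extratrees",
                                 seed = derive_seed(seed, "etr"),
                                 num.threads = 1),
    dt = rpart::rpart(y ~ ., data = data.frame(y = y, X),
                      method = "class"),
    lr = nnet::multinom(y ~ ., data = data.frame(y = y, X), trace = FALSE,
                        maxit = 200, MaxNWts = 100000),
    nb = e1071::naiveBayes(x = X, y = y),
    lda = MASS::lda(X, grouping = y),
    mlp = nnet::nnet(X, nnet::class.ind(y), size = 16, decay = 1e-3,
                     maxit = 200, softmax = TRUE, trace = FALSE,
                     MaxNWts = 100000),
    svm = e1071::svm(X, y, probability = TRUE),
    glmnet = glmnet::glmnet(X, y, family = "multinomial", lambda = 0.01),
    gbt = fit_gbt(X, as.integer(y) - 1L, nlevels(y), seed = seed),
    linear_boost = fit_gbt(X, as.integer(y) - 1L, nlevels(y), seed = seed,
                           booster = "gblinear", nrounds = 50L),
    stop("unknown roster model: ", name)
  ))
  structure(list(name = name, fit = fit, levels = levels(y)),
            class = "roster_model")
}

# Gradient-boosted tree classifier used as the boosted-ensemble roster
# entry, the RFE wrapper and the genetic-algorithm fitness model
# (100 rounds, depth 3 by default).
fit_gbt <- function(X, y_int, n_class, seed = 1, nrounds = 100L,
                    max_depth = 3L, booster = "gbtree") {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  params <- list(objective = "multi:softprob", num_class = n_class,
                 nthread = 1, seed = derive_seed(seed, "xgb"),
                 booster = booster)
  if (booster == "gbtree") params$max_depth <- max_depth
  m <- xgboost::xgb.train(params = params,
                          data = xgboost::xgb.DMatrix(X, label = y_int,
                                                      nthread = 1),
                          nrounds = nrounds, verbose = 0)
  list(model = m, n_class = n_class, p = ncol(X))
}

predict_gbt <- function(fit, X) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1))
  matrix(p, ncol = fit$n_class)
}

# Per-class probability matrix (rows = samples, cols = training levels).
predict_roster_model <- function(model, X) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  lv <- model$levels
  prob <- switch(model$name,
    knn = knn_prob(model$fit, X),
    rf = predict(model$fit, data = X, num.threads = 1)$predictions,
    extra_trees = predict(model$fit, data = X, num.threads = 1)$predictions,
    dt = predict(model$fit, newdata = data.frame(X), type = "prob"),
    lr = {
      p <- predict(model$fit, newdata = data.frame(X), type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p)
      p
    },
    nb = predict(model$fit, newdata = X, type = "raw"),
    lda = predict(model$fit, newdata = X)$posterior,
    mlp = predict(model$fit, newdata = X),
    svm = attr(predict(model$fit, newdata = X, probability = TRUE),
               "probabilities")[, lv, drop = FALSE],
    glmnet = {
      p <- predict(model$fit, newx = X, type = "response")
      matrix(p[, , 1], ncol = length(lv), dimnames = list(NULL, dimnames(p)[[2]]))
    },
    gbt = predict_gbt(model$fit, X),
    linear_boost = predict_gbt(model$fit, X)
  )
  prob <- as.matrix(prob)
  if (!is.null(colnames(prob)) && all(lv %in% colnames(prob))) {
    prob <- prob[, lv, drop = FALSE]
  }
  colnames(prob) <- lv
  prob
}

# k-NN with vote-fraction probabilities (small-n usage only).
knn_prob <- function(fit, Xnew) {
  tr <- fit$X; y <- fit$y; k <- min(fit$k, nrow(tr))
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(Xnew)), rowSums(tr^2)) - 2 * Xnew %*% t(tr)
  lv <- levels(y)
  t(apply(d2, 1, function(row) {
    nb <- y[order(row)[seq_len(k)]]
    tabulate(as.integer(nb), nbins = length(lv)) / k
  }))
}

# Seeded stratified fold assignment; errors when a class has fewer members
# than folds.
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (min(table(y)) < k) {
    stop("stratification infeasible: smallest class has fewer than k members")
  }
  folds <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validate the model roster
#'
#' Stratified k-fold cross-validation of each roster model, scoring the
#' eight macro metrics per fold and reporting fold means and standard
#' deviations. The report is sorted by the primary metric (macro F1 by
#' default), ties broken by macro MCC.
#'
#' @param X numeric feature matrix
#' @param y class labels (factor or character)
#' @param models roster subset to evaluate
#' @param k number of folds (default 10)
#' @param seed integer seed for fold assignment and model fits
#' @param primary_metric column used for ranking
#' @return data frame with one row per model: `<metric>_mean` and
#'   `<metric>_sd` for REC, SPEC, ACC, PREC, F1, MCC, AUC, AUPR
#' @export
cross_validate_models <- function(X, y, models = model_roster(), k = 10,
                                  seed = 1, primary_metric = "F1") {
  stopifnot(all(models %in% model_roster()))
  y <- droplevels(as.factor(y))
  folds <- stratified_folds(y, k, seed)
  metric_names <- c("REC", "SPEC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")
  rows <- lapply(models, function(nm) {
    per_fold <- vapply(seq_len(k), function(fi) {
      tr <- folds != fi
      fit <- fit_roster_model(nm, X[tr, , drop = FALSE], y[tr],
                              seed = derive_seed(seed, nm, fi))
      prob <- predict_roster_model(fit, X[!tr, , drop = FALSE])
      rep <- metric_report(as.integer(y[!tr]) - 1L,
                           scores = prob,
                           n_classes = nlevels(y))
      unlist(rep[metric_names])
    }, numeric(length(metric_names)))
    stats <- c(rowMeans(per_fold), apply(per_fold, 1, stats::sd))
    names(stats) <- c(paste0(metric_names, "_mean"), paste0(metric_names, "_sd"))
    c(list(model = nm), as.list(stats))
  })
  report <- do.call(rbind, lapply(rows, as.data.frame))
  ord <- order(report[[paste0(primary_metric, "_mean")]],
               report$MCC_mean, decreasing = TRUE)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  report
}

## ---- RFE -------------------------------------------------------------

# Wrapper models that expose per-feature importance scores.
rfe_wrappers <- function() c("gbt", "rf", "extra_trees")

# Feature importances from one wrapper fit; zero for unused features.
wrapper_importance <- function(wrapper, X, y, seed, nrounds) {
  if (wrapper == "gbt") {
    fit <- fit_gbt(X, as.integer(y) - 1L, nlevels(y), seed = seed,
                   nrounds = nrounds)
    imp <- xgboost::xgb.importance(model = fit$model)
    gain <- numeric(ncol(X))
    if (nrow(imp) > 0) {
      pos <- as.integer(sub("^f", "", imp$Feature))
      gain[pos] <- imp$Gain
    }
    return(gain)
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = X, y = y, num.trees = max(100L, nrounds),
                        importance = "impurity", num.threads = 1,
                        splitrule = if (wrapper == "extra_trees")
                          "extratrees" else "gini",
                        seed = derive_seed(seed, "ranger-imp"))
  unname(fit$variable.importance)
}

#' Recursive feature elimination with a gradient-boosted wrapper
#'
#' Starting from all columns, the wrapper is refitted on the surviving
#' subset and the least important features are dropped until `target_k`
#' remain. While more than `fine_factor * target_k` columns survive, a
#' fraction `step` of the remainder is dropped per iteration; after that,
#' features are removed one at a time, matching the canonical
#' single-elimination loop. Subsets are strictly nested; the full
#' elimination order is recorded.
#'
#' @param X numeric feature matrix
#' @param y class labels
#' @param target_k number of features to keep
#' @param wrapper wrapper model; one of `"gbt"` (gradient-boosted trees,
#'   importance = split gain, the default), `"rf"` or `"extra_trees"`
#'   (impurity importance); roster models without importance scores are
#'   rejected
#' @param step fraction of surviving features dropped per coarse iteration
#' @param fine_factor multiple of `target_k` below which elimination
#'   becomes single-feature
#' @param seed integer seed for wrapper fits
#' @param nrounds boosting rounds per wrapper fit
#' @return an `rfe_result`: `selected` (sorted column indices),
#'   `eliminated_order` (first-dropped first), `n_fits`
#' @export
rfe_select <- function(X, y, target_k, wrapper = "gbt", step = 0.1,
                       fine_factor = 2, seed = 1, nrounds = 50L) {
  if (!wrapper %in% rfe_wrappers()) {
    stop("wrapper '", wrapper, "' does not expose feature importances; ",
         "use one of: ", paste(rfe_wrappers(), collapse = ", "))
  }
  p <- ncol(X)
  stopifnot(target_k >= 1, target_k <= p)
  y <- droplevels(as.factor(y))
  surviving <- seq_len(p)
  eliminated <- integer(0)
  n_fits <- 0L
  while (length(surviving) > target_k) {
    n_drop <- if (length(surviving) > fine_factor * target_k) {
      max(1L, min(floor(step * length(surviving)),
                  length(surviving) - target_k))
    } else 1L
    gain <- wrapper_importance(wrapper, X[, surviving, drop = FALSE], y,
                               seed = derive_seed(seed, "rfe", n_fits),
                               nrounds = nrounds)
    n_fits <- n_fits + 1L
    # least important first; ties broken by column order
    drop_local <- order(gain, seq_along(gain))[seq_len(n_drop)]
    eliminated <- c(eliminated, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  structure(list(selected = sort(surviving),
                 eliminated_order = eliminated,
                 n_fits = n_fits,
                 target_k = target_k,
                 wrapper = wrapper),
            class = "rfe_result")
}
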