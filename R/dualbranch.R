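# The dual-branch fusion classifier: a convolutional image branch
# (backbone -> 1000-dim embedding -> 512 -> 256 head) and a feedforward
# branch over the 512 selected handcrafted features (512 -> 256 -> 128),
# concatenated (384) and classified through 256 -> 128 -> C fully
# connected layers. Every hidden linear layer is followed by batch
# normalisation, ReLU and dropout; the final layer emits raw class scores.

#' Dual-branch architecture configuration
#'
#' @param backbone image backbone identifier; `"small"` (default) is the
#'   package's compact convolutional backbone trained from random
#'   initialisation, suitable for offline use; a custom backbone can be
#'   supplied to [build_dual_branch()] via `backbone_layers`
#' @param feature_dim handcrafted-feature input width (the selection
#'   stage's target k)
#' @param fnn_dims widths of the feedforward branch, input first
#' @param cnn_head_dims widths of the dense head on the backbone
#'   embedding, input (backbone output) first
#' @param fusion_dims widths of the fusion classifier, input first and
#'   `num_classes` last; the input width must equal the sum of the two
#'   branch output widths
#' @param dropout dropout rate after every hidden linear layer
#' @param num_classes output classes
#' @param image_size square input resolution of the image branch
#' @param branches `"both"`, `"fnn_only"` or `"cnn_only"` (ablations)
#' @return a `dual_branch_config` list
#' @export
dual_branch_config <- function(backbone = "small",
                               feature_dim = 512,
                               fnn_dims = c(512, 256, 128),
                               cnn_head_dims = c(1000, 512, 256),
                               fusion_dims = c(384, 256, 128, 4),
                               dropout = 0.2,
                               num_classes = 4,
                               image_size = 64,
                               branches = "both") {
  stopifnot(fnn_dims[1] == feature_dim,
            fusion_dims[length(fusion_dims)] == num_classes,
            branches %in% c("both", "fnn_only", "cnn_only"))
  fnn_out <- fnn_dims[length(fnn_dims)]
  cnn_out <- cnn_head_dims[length(cnn_head_dims)]
  expected <- switch(branches,
                     both = fnn_out + cnn_out,
                     fnn_only = fnn_out,
                     cnn_only = cnn_out)
  if (fusion_dims[1] != expected) {
    stop("fusion input width ", fusion_dims[1],
         " does not match branch outputs (FNN ", fnn_out, " + CNN ",
         cnn_out, " for branches='", branches, "', expected ", expected, ")")
  }
  structure(list(backbone = backbone, feature_dim = feature_dim,
                 fnn_dims = fnn_dims, cnn_head_dims = cnn_head_dims,
                 fusion_dims = fusion_dims, dropout = dropout,
                 num_classes = num_classes, image_size = image_size,
                 branches = branches),
            class = "dual_branch_config")
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, initial learning
#' rate 1e-4, 96 epochs, batch size 32, softmax cross-entropy loss.
#'
#' @param lr initial Adam learning rate
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param seed integer seed for shuffling, dropout and initialisation
#' @return a `train_config` list
#' @export
train_config <- function(lr = 1e-4, epochs = 96, batch_size = 32, seed = 1) {
  stopifnot(lr > 0 || lr == 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, epochs = epochs, batch_size = batch_size,
                 seed = seed),
            class = "train_config")
}

# Hidden dense block: linear -> batchnorm -> relu -> dropout.
dense_block <- function(d_in, d_out, dropout) {
  list(nn_linear(d_in, d_out), nn_batchnorm(d_out), nn_relu(),
       nn_dropout(dropout))
}

dense_stack <- function(dims, dropout) {
  out <- list()
  for (i in seq_len(length(dims) - 1)) {
    out <- c(out, dense_block(dims[i], dims[i + 1], dropout))
  }
  out
}

# Compact convolutional backbone: four 3x3 conv/ReLU stages with
# max-pooling, global average pooling, and a linear embedding layer to
# 1000 units. The last convolution is the class-activation target layer.
small_backbone <- function(image_size, out_dim = 1000) {
  list(layers = list(nn_conv(3, 3, 8), nn_relu(), nn_maxpool(),
                     nn_conv(3, 8, 16), nn_relu(), nn_maxpool(),
                     nn_conv(3, 16, 32), nn_relu(), nn_maxpool(),
                     nn_conv(3, 32, 64), nn_relu(),
                     nn_gap(), nn_linear(64, out_dim)),
       last_conv_act = 11L)  # index of the ReLU after the last conv
}

#' Build the dual-branch model
#'
#' @param config a [dual_branch_config()]
#' @param seed integer seed for weight initialisation
#' @param backbone_layers optional custom backbone: a list with `layers`
#'   (layer list consuming an (H, W, 3, B) array and emitting a
#'   (B, cnn_head_dims[1]) matrix) and `last_conv_act` (index of its last
#'   convolutional activation)
#' @return a `dual_branch_model`
#' @export
build_dual_branch <- function(config = dual_branch_config(), seed = 1,
                              backbone_layers = NULL) {
  stopifnot(inherits(config, "dual_branch_config"))
  with_seed(derive_seed(seed, "build"), {
    use_cnn <- config$branches != "fnn_only"
    use_fnn <- config$branches != "cnn_only"
    backbone <- NULL
    if (use_cnn) {
      backbone <- backbone_layers %||%
        small_backbone(config$image_size, out_dim = config$cnn_head_dims[1])
    }
    groups <- list(
      backbone = if (use_cnn) backbone$layers else list(),
      cnn_head = if (use_cnn) dense_stack(config$cnn_head_dims,
                                          config$dropout) else list(),
      fnn = if (use_fnn) dense_stack(config$fnn_dims, config$dropout)
            else list(),
      fusion = c(dense_stack(fusion_hidden(config), config$dropout),
                 list(nn_linear(fusion_hidden(config)[length(fusion_hidden(config))],
                                config$num_classes)))
    )
    structure(list(groups = groups, config = config,
                   last_conv_act = if (use_cnn) backbone$last_conv_act
                                   else NA_integer_,
                   feature_center = NULL, feature_scale = NULL,
                   image_center = NULL, image_scale = NULL),
              class = "dual_branch_model")
  })
}

# Fusion dims without the final class layer (hidden widths only).
fusion_hidden <- function(config) {
  config$fusion_dims[-length(config$fusion_dims)]
}

#' Layer widths of a built model
#'
#' Introspects the dense layers of each branch; used to audit the
#' architecture against its specification.
#'
#' @param model a `dual_branch_model`
#' @return list with `fnn`, `cnn_head` and `fusion` width vectors and
#'   `dropout_after_hidden`, the dropout rates following each hidden
#'   linear layer
#' @export
model_layer_widths <- function(model) {
  widths <- function(layers, add_out = FALSE) {
    lin <- Filter(function(l) l$type == "linear", layers)
    if (length(lin) == 0) return(numeric(0))
    c(vapply(lin, function(l) l$d_in, numeric(1)),
      lin[[length(lin)]]$d_out)
  }
  drops <- function(layers) {
    out <- numeric(0)
    for (i in seq_along(layers)) {
      if (layers[[i]]$type == "linear" && i + 3 <= length(layers) &&
          layers[[i + 3]]$type == "dropout") {
        out <- c(out, layers[[i + 3]]$p)
      }
    }
    out
  }
  list(fnn = widths(model$groups$fnn),
       cnn_head = widths(model$groups$cnn_head),
       fusion = widths(model$groups$fusion),
       dropout_after_hidden = c(drops(model$groups$fnn),
                                drops(model$groups$cnn_head),
                                drops(model$groups$fusion)))
}

# Standardise images / features with the model's stored training statistics.
prep_images <- function(model, images) {
  if (is.null(model$image_center)) return(images)
  sweep(sweep(images, 3, model$image_center), 3,
        model$image_scale, "/")
}

prep_features <- function(model, features) {
  if (is.null(model$feature_center)) return(features)
  sweep(sweep(features, 2, model$feature_center), 2,
        model$feature_scale, "/")
}

#' Forward pass of the dual-branch model
#'
#' @param model a `dual_branch_model`
#' @param images (H, W, 3, B) array of image-branch inputs in `[0, 1]`
#'   (ignored for `fnn_only` models)
#' @param features (B, feature_dim) matrix of selected handcrafted
#'   features (ignored for `cnn_only` models)
#' @param training enable batch statistics and dropout
#' @return list: `logits` (B x C raw scores) and `caches` for backward
#' @export
model_forward <- function(model, images = NULL, features = NULL,
                          training = FALSE) {
  cfg <- model$config
  use_cnn <- cfg$branches != "fnn_only"
  use_fnn <- cfg$branches != "cnn_only"
  caches <- list()
  outs <- list()
  if (use_fnn) {
    stopifnot(!is.null(features))
    if (ncol(features) != cfg$feature_dim) {
      stop("feature width ", ncol(features), " != configured ",
           cfg$feature_dim)
    }
    f <- seq_forward(model$groups$fnn, prep_features(model, features),
                     training)
    caches$fnn <- f$caches
    outs$fnn <- f$out
  }
  if (use_cnn) {
    stopifnot(!is.null(images))
    bb <- seq_forward(model$groups$backbone, prep_images(model, images),
                      training)
    hd <- seq_forward(model$groups$cnn_head, bb$out, training)
    caches$backbone <- bb$caches
    caches$cnn_head <- hd$caches
    outs$cnn <- hd$out
  }
  if (use_fnn && use_cnn) {
    if (nrow(outs$fnn) != nrow(outs$cnn)) stop("branch batch sizes differ")
  }
  fused <- do.call(cbind, outs[c("fnn", "cnn")[c(use_fnn, use_cnn)]])
  fz <- seq_forward(model$groups$fusion, fused, training)
  caches$fusion <- fz$caches
  caches$fused_width_fnn <- if (use_fnn) ncol(outs$fnn) else 0L
  list(logits = fz$out, caches = caches)
}

# Full backward pass; returns per-group parameter gradients.
model_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  use_cnn <- cfg$branches != "fnn_only"
  use_fnn <- cfg$branches != "cnn_only"
  fz <- seq_backward(model$groups$fusion, caches$fusion, dlogits)
  grads <- list(fusion = fz$grads)
  wf <- caches$fused_width_fnn
  if (use_fnn) {
    dfnn <- fz$dx[, seq_len(wf), drop = FALSE]
    grads$fnn <- seq_backward(model$groups$fnn, caches$fnn, dfnn)$grads
  }
  if (use_cnn) {
    dcnn <- fz$dx[, (wf + 1):ncol(fz$dx), drop = FALSE]
    hd <- seq_backward(model$groups$cnn_head, caches$cnn_head, dcnn)
    grads$cnn_head <- hd$grads
    grads$backbone <- seq_backward(model$groups$backbone, caches$backbone,
                                   hd$dx)$grads
  }
  grads
}

#' Predict class probabilities and labels
#'
#' The network is trained on raw scores with softmax cross-entropy;
#' reported probabilities use the configured output activation. The
#' `"sigmoid"` mode applies an independent logistic to each class score
#' (rows then no longer sum to one); both modes share the same argmax.
#'
#' @param model a trained `dual_branch_model`
#' @param images (H, W, 3, B) array (omit for `fnn_only`)
#' @param features (B, feature_dim) matrix (omit for `cnn_only`)
#' @param activation `"softmax"` (default) or `"sigmoid"`
#' @return list: `prob` (B x C), `labels` (0-based integer argmax),
#'   `logits`
#' @export
predict_dual_branch <- function(model, images = NULL, features = NULL,
                                activation = c("softmax", "sigmoid")) {
  activation <- match.arg(activation)
  logits <- model_forward(model, images, features, training = FALSE)$logits
  prob <- if (activation == "softmax") {
    e <- exp(logits - apply(logits, 1, max))
    e / rowSums(e)
  } else {
    1 / (1 + exp(-logits))
  }
  list(prob = prob, labels = max.col(logits, ties.method = "first") - 1L,
       logits = logits)
}

# Deep-copy parameter extraction / restoration for checkpointing.
get_params <- function(model) model$groups
set_params <- function(model, groups) { model$groups <- groups; model }

#' Train the dual-branch model
#'
#' Minibatch Adam on softmax cross-entropy. Handcrafted features are
#' standardised with training-set statistics stored on the model; image
#' channels likewise. Per-epoch loss, accuracy and macro F1 are recorded
#' for both splits and the checkpoint with the best validation macro F1 is
#' returned.
#'
#' @param train_data list with `images` (H, W, 3, N array, `[0, 1]`),
#'   `features` (N x feature_dim), `labels` (0-based integers)
#' @param val_data same structure for the validation split
#' @param config a [dual_branch_config()]
#' @param tcfg a [train_config()]
#' @param backbone_layers optional custom backbone (see
#'   [build_dual_branch()])
#' @return list: `model` (best-validation checkpoint), `final_model`,
#'   `history` (data frame, one row per epoch)
#' @export
train_dual_branch <- function(train_data, val_data, config = dual_branch_config(),
                              tcfg = train_config(),
                              backbone_layers = NULL) {
  cfg <- config
  use_cnn <- cfg$branches != "fnn_only"
  use_fnn <- cfg$branches != "cnn_only"
  y <- as.integer(train_data$labels)
  if (length(unique(y)) < cfg$num_classes) {
    stop("a class is absent from the training split")
  }
  model <- build_dual_branch(cfg, seed = tcfg$seed,
                             backbone_layers = backbone_layers)
  if (use_fnn) {
    mu <- colMeans(train_data$features)
    sdv <- matrixStats_colSds(train_data$features)
    model$feature_center <- mu
    model$feature_scale <- ifelse(sdv > 1e-8, sdv, 1)
  }
  if (use_cnn) {
    model$image_center <- vapply(1:3, function(ch) {
      mean(train_data$images[, , ch, ])
    }, numeric(1))
    model$image_scale <- vapply(1:3, function(ch) {
      s <- stats::sd(as.vector(train_data$images[, , ch, ]))
      if (s > 1e-8) s else 1
    }, numeric(1))
  }
  state <- adam_init(model$groups)
  n <- length(y)
  step <- 0L
  history <- data.frame()
  best_f1 <- -Inf
  best_groups <- model$groups
  eval_split <- function(data) {
    pr <- predict_dual_branch(model,
                              images = if (use_cnn) data$images else NULL,
                              features = if (use_fnn) data$features else NULL)
    yv <- as.integer(data$labels)
    sm <- softmax_xent(pr$logits, yv)
    rep <- metric_report(yv, y_pred = pr$labels, n_classes = cfg$num_classes)
    c(loss = sm$loss, acc = mean(pr$labels == yv), f1 = rep$F1)
  }
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, "shuffle", epoch),
                     sample.int(n))
    train_loss <- 0; train_correct <- 0L
    train_pred <- integer(n); train_true <- integer(n)
    pos <- 0L
    for (start in seq(1, n, by = tcfg$batch_size)) {
      idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      step <- step + 1L
      res <- with_seed(derive_seed(tcfg$seed, "step", step), {
        fw <- model_forward(model,
                            images = if (use_cnn)
                              train_data$images[, , , idx, drop = FALSE]
                              else NULL,
                            features = if (use_fnn)
                              train_data$features[idx, , drop = FALSE]
                              else NULL,
                            training = TRUE)
        sm <- softmax_xent(fw$logits, y[idx])
        grads <- model_backward(model, fw$caches, sm$dlogits)
        list(fw = fw, sm = sm, grads = grads)
      })
      for (gname in names(model$groups)) {
        if (length(model$groups[[gname]]) == 0) next
        cache_name <- gname
        if (!is.null(res$fw$caches[[cache_name]])) {
          model$groups[[gname]] <- update_bn_stats(model$groups[[gname]],
                                                   res$fw$caches[[cache_name]])
        }
        if (!is.null(res$grads[[gname]]) && tcfg$lr > 0) {
          upd <- adam_update(model$groups[[gname]], res$grads[[gname]],
                             state[[gname]], tcfg$lr, step)
          model$groups[[gname]] <- upd$layers
          state[[gname]] <- upd$state
        }
      }
      bpred <- max.col(res$fw$logits, ties.method = "first") - 1L
      train_loss <- train_loss + res$sm$loss * length(idx)
      train_correct <- train_correct + sum(bpred == y[idx])
      train_pred[pos + seq_along(idx)] <- bpred
      train_true[pos + seq_along(idx)] <- y[idx]
      pos <- pos + length(idx)
    }
    tr_f1 <- metric_report(train_true, y_pred = train_pred,
                           n_classes = cfg$num_classes)$F1
    va <- eval_split(val_data)
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = train_loss / n, train_acc = train_correct / n,
      train_f1 = tr_f1,
      val_loss = va[["loss"]], val_acc = va[["acc"]], val_f1 = va[["f1"]]))
    if (va[["f1"]] > best_f1) {
      best_f1 <- va[["f1"]]
      best_groups <- model$groups
    }
  }
  final_model <- model
  best_model <- set_params(model, best_groups)
  list(model = best_model, final_model = final_model, history = history)
}
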