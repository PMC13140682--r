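# End-to-end orchestration: synthesis -> feature extraction -> Yeo-Johnson
# -> RFE -> augmentation pool -> genetic selection -> dual-branch training
# -> evaluation -> class-activation overlay. Every stage writes plain-file
# artifacts into the run directory so stages can be inspected and rerun
# independently; one master seed governs all stage sub-seeds.

#' Pipeline configuration
#'
#' Defaults define the package's reference synthetic study: 50 images per
#' class at 128 x 128, a 10 % test / 20 % validation stratified split,
#' one augmentation candidate per source image, a genetic algorithm
#' selecting 60 of them, RFE down to 512 features and a 5-epoch training
#' run of the compact backbone at 64 x 64.
#'
#' @param n_per_class synthetic images per class
#' @param image_size synthetic image side
#' @param test_fraction,val_fraction split fractions
#' @param per_image augmentation candidates per source image
#' @param ga a [ga_config()] (its `sample_size` is the D1 size)
#' @param fitness_resize image side for the GA fitness representation
#' @param target_k features kept by RFE (the FNN input width)
#' @param rfe_nrounds boosting rounds per RFE wrapper fit
#' @param model a [dual_branch_config()]
#' @param training a [train_config()]
#' @param use_ga include the augmentation + genetic-selection stage; when
#'   `FALSE` the model trains on the training split alone
#' @param seed master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_per_class = 50,
                            image_size = 128,
                            test_fraction = 0.1,
                            val_fraction = 0.2,
                            per_image = 1,
                            ga = ga_config(generations = 5, pop_size = 6,
                                           sample_size = 60, elite = 2,
                                           mutation_rate = 0.1),
                            fitness_resize = 32,
                            target_k = 512,
                            rfe_nrounds = 30L,
                            model = dual_branch_config(),
                            training = train_config(lr = 2e-3, epochs = 5,
                                                    batch_size = 16),
                            use_ga = TRUE,
                            seed = 1) {
  structure(list(n_per_class = n_per_class, image_size = image_size,
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 per_image = per_image, ga = ga,
                 fitness_resize = fitness_resize, target_k = target_k,
                 rfe_nrounds = rfe_nrounds, model = model,
                 training = training, use_ga = use_ga, seed = seed),
            class = "pipeline_config")
}

label_int <- function(labels) {
  as.integer(factor(labels, levels = class_labels())) - 1L
}

# Assemble the (images, features, labels) tensors for a list of images
# given a global feature matrix indexed by source_id.
model_inputs <- function(images, feat_matrix, feat_ids, selected, image_size) {
  ids <- dataset_ids(images)
  rows <- match(ids, feat_ids)
  stopifnot(!anyNA(rows))
  arr <- array(0, dim = c(image_size, image_size, 3, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]$pixels / 255
    if (dim(img)[1] != image_size) {
      img <- resize_bilinear(img, image_size, image_size)
    }
    arr[, , , i] <- img
  }
  list(images = arr,
       features = feat_matrix[rows, selected, drop = FALSE],
       labels = label_int(dataset_labels(images)))
}

#' Run the full pipeline
#'
#' Executes synthesis, splitting, feature extraction, Yeo-Johnson fitting
#' (training rows only), RFE, augmentation-pool generation, genetic
#' selection, dual-branch training on training + selected images,
#' evaluation on validation and test splits, and a class-activation
#' overlay for one test image. Artifacts (manifests, JSON reports, CSV
#' history, PNG overlay, run log) are written under `out_dir`.
#'
#' @param config a [pipeline_config()]
#' @param out_dir artifact directory (created if missing)
#' @return list with the trained `model`, `reports` (validation and test
#'   [metric_report()]s), `history`, `selection` (RFE result), `ga`
#'   (fitness history) and `paths` of written artifacts
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- c(sprintf("run started %s", format(Sys.time())),
                 sprintf("master seed %d", seed))

  dataset <- generate_synthetic_dataset(config$n_per_class,
                                        size = config$image_size,
                                        seed = derive_seed(seed, "synth"))
  split <- stratified_split(dataset, config$test_fraction,
                            config$val_fraction,
                            seed = derive_seed(seed, "split"))
  log_lines <- c(log_lines, sprintf("split sizes train=%d val=%d test=%d",
                                    length(split$train),
                                    length(split$validation),
                                    length(split$test)))

  # augmentation + genetic selection (on training + validation sources)
  d1 <- list()
  ga_out <- NULL
  if (config$use_ga) {
    ga_cfg <- config$ga
    ga_cfg$seed <- derive_seed(seed, "ga")
    ga_out <- select_augmented(c(split$train, split$validation), ga_cfg,
                               per_image = config$per_image,
                               fitness_resize = config$fitness_resize)
    d1 <- ga_out$selected_images
    jsonlite::write_json(list(history = ga_out$history,
                              fitness = ga_out$fitness,
                              selected = ga_out$selected_indices),
                         file.path(out_dir, "ga_selection.json"),
                         auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf("ga selected %d images, fitness %.4f",
                                      length(d1), ga_out$fitness))
  }
  sets <- dataset_compositions(split, d1)
  train_imgs <- sets$D2  # Training + D1 (Training only when GA disabled)

  # handcrafted features for every image the run touches
  all_imgs <- c(dataset, d1)
  feats <- extract_features(all_imgs, seed = derive_seed(seed, "features"))
  feat_ids <- dataset_ids(all_imgs)

  train_rows <- match(dataset_ids(split$train), feat_ids)
  yj <- fit_yeo_johnson(feats[train_rows, , drop = FALSE])
  featsT <- apply_yeo_johnson(feats, yj)

  rfe <- rfe_select(featsT[train_rows, , drop = FALSE],
                    dataset_labels(split$train),
                    target_k = config$target_k,
                    seed = derive_seed(seed, "rfe"),
                    nrounds = config$rfe_nrounds)
  jsonlite::write_json(list(indices = rfe$selected,
                            target_k = rfe$target_k,
                            wrapper = "gbt",
                            seed = derive_seed(seed, "rfe")),
                       file.path(out_dir, "selected_features.json"),
                       digits = NA)
  log_lines <- c(log_lines, sprintf("rfe kept %d of %d features (%d fits)",
                                    length(rfe$selected), ncol(feats),
                                    rfe$n_fits))

  mk <- function(imgs) model_inputs(imgs, featsT, feat_ids, rfe$selected,
                                    config$model$image_size)
  tr <- mk(train_imgs)
  va <- mk(split$validation)
  te <- mk(split$test)

  tcfg <- config$training
  tcfg$seed <- derive_seed(seed, "train")
  fit <- train_dual_branch(tr, va, config$model, tcfg)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  use_cnn <- config$model$branches != "fnn_only"
  use_fnn <- config$model$branches != "cnn_only"
  eval_on <- function(data) {
    pr <- predict_dual_branch(fit$model,
                              images = if (use_cnn) data$images else NULL,
                              features = if (use_fnn) data$features else NULL)
    metric_report(data$labels, y_pred = pr$labels, scores = pr$prob)
  }
  rep_val <- eval_on(va)
  rep_test <- eval_on(te)
  metric_names <- c("REC", "SPEC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")
  jsonlite::write_json(list(validation = rep_val[metric_names],
                            test = rep_test[metric_names]),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  overlay_path <- NA_character_
  if (use_cnn) {
    ti <- 1L
    hm <- gradcam(fit$model,
                  array(te$images[, , , ti], dim = dim(te$images)[1:3]),
                  features = if (use_fnn) te$features[ti, ] else NULL)
    ov <- overlay(array(as.integer(round(te$images[, , , ti] * 255)),
                        dim = dim(te$images)[1:3]), hm)
    overlay_path <- file.path(out_dir, "overlay.png")
    write_image_png(ov, overlay_path)
    hm255 <- as.integer(round(hm$values * 255))
    write_image_png(array(rep(hm255, 3), dim = c(dim(hm$values), 3)),
                    file.path(out_dir, "heatmap.png"))
  }

  man_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(c(dataset, d1), file.path(out_dir, "images"), man_path)
  digests <- tools::md5sum(c(man_path,
                             file.path(out_dir, "selected_features.json"),
                             file.path(out_dir, "evaluation.json")))
  log_lines <- c(log_lines,
                 sprintf("digest %s %s", basename(names(digests)), digests),
                 sprintf("val F1 %.4f test F1 %.4f", rep_val$F1, rep_test$F1))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  list(model = fit$model, history = fit$history,
       reports = list(validation = rep_val, test = rep_test),
       selection = rfe, ga = ga_out, split = split,
       paths = list(dir = out_dir, overlay = overlay_path,
                    evaluation = file.path(out_dir, "evaluation.json")))
}

#' Ablation study over model variants
#'
#' Trains the requested variants on identical splits, features and seeds
#' and reports their macro metrics side by side. Modes: `"full"` (both
#' branches), `"fnn_only"`, `"cnn_only"` and `"no_augmentation"` (full
#' model without the genetic-augmentation stage).
#'
#' @param config a [pipeline_config()]
#' @param modes character vector of variant names
#' @param out_dir artifact directory
#' @return list: `table` (one row of macro metrics per mode), `runs`
#' @export
ablate <- function(config = pipeline_config(),
                   modes = c("full", "fnn_only", "cnn_only"),
                   out_dir = tempfile("ablate")) {
  known <- c("full", "fnn_only", "cnn_only", "no_augmentation")
  if (!all(modes %in% known)) {
    stop("unknown ablation mode(s): ",
         paste(setdiff(modes, known), collapse = ", "))
  }
  runs <- lapply(modes, function(mode) {
    cfg <- config
    if (mode %in% c("fnn_only", "cnn_only")) {
      mc <- cfg$model
      fnn_out <- mc$fnn_dims[length(mc$fnn_dims)]
      cnn_out <- mc$cnn_head_dims[length(mc$cnn_head_dims)]
      mc$branches <- mode
      mc$fusion_dims[1] <- if (mode == "fnn_only") fnn_out else cnn_out
      cfg$model <- do.call(dual_branch_config,
                           unclass(mc)[names(formals(dual_branch_config))])
    }
    if (mode == "no_augmentation") cfg$use_ga <- FALSE
    run_pipeline(cfg, out_dir = file.path(out_dir, mode))
  })
  names(runs) <- modes
  metric_names <- c("REC", "SPEC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")
  tab <- do.call(rbind, lapply(modes, function(m) {
    as.data.frame(c(list(mode = m),
                    runs[[m]]$reports$test[metric_names]))
  }))
  utils::write.csv(tab, file.path(out_dir, "ablation.csv"), row.names = FALSE)
  list(table = tab, runs = runs)
}
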