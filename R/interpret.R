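# Gradient-weighted class-activation heatmaps: the gradient of a class
# score with respect to the backbone's last convolutional activation,
# spatially averaged into channel weights, rectified-weighted-summed into
# a map, upsampled to the input resolution and min-max normalised.

#' Gradient-weighted class-activation heatmap
#'
#' @param model a `dual_branch_model` with an image branch
#' @param image H x W x 3 array in `[0, 1]` (the image-branch input
#'   resolution) or a `labeled_image` (resized automatically)
#' @param features length-`feature_dim` numeric vector of the image's
#'   selected handcrafted features (required unless the model is
#'   `cnn_only`)
#' @param target_class 0-based class index; defaults to the model's
#'   predicted class
#' @return a `heatmap` list: `values` (H x W in `[0, 1]`), `target_class`,
#'   `weights` (per-channel), `raw` (pre-normalisation rectified map)
#' @export
gradcam <- function(model, image, features = NULL, target_class = NULL) {
  cfg <- model$config
  if (cfg$branches == "fnn_only") {
    stop("model has no convolutional branch with spatial activations")
  }
  if (inherits(image, "labeled_image")) image <- image$pixels / 255
  if (dim(image)[1] != cfg$image_size) {
    image <- resize_bilinear(image, cfg$image_size, cfg$image_size)
  }
  images <- array(image, dim = c(dim(image), 1))
  feat_mat <- NULL
  if (cfg$branches == "both") {
    stopifnot(!is.null(features))
    feat_mat <- matrix(features, nrow = 1)
  }
  fw <- model_forward(model, images = images, features = feat_mat,
                      training = FALSE)
  if (is.null(target_class)) {
    target_class <- which.max(fw$logits[1, ]) - 1L
  }
  dlogits <- matrix(0, 1, cfg$num_classes)
  dlogits[1, target_class + 1L] <- 1

  # backward to the last convolutional activation
  fz <- seq_backward(model$groups$fusion, fw$caches$fusion, dlogits)
  wf <- fw$caches$fused_width_fnn
  dcnn <- fz$dx[, (wf + 1):ncol(fz$dx), drop = FALSE]
  hd <- seq_backward(model$groups$cnn_head, fw$caches$cnn_head, dcnn)
  stop_at <- model$last_conv_act
  bb <- seq_backward(model$groups$backbone, fw$caches$backbone, hd$dx,
                     stop_after = stop_at)
  grad_act <- bb$dx  # (h, w, C, 1) gradient at the activation
  # recover the activation itself from the next layer's cache
  act <- activation_at(model, fw$caches$backbone, stop_at, images)

  wts <- apply(grad_act[, , , 1, drop = FALSE], 3, mean)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (ch in seq_along(wts)) {
    cam <- cam + wts[ch] * act[, , ch, 1]
  }
  cam <- pmax(cam, 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  cam_up <- resize_bilinear(array(cam, dim = c(dim(cam), 1)), h, w)[, , 1]
  rng <- range(cam_up)
  values <- if (rng[2] > rng[1]) {
    (cam_up - rng[1]) / (rng[2] - rng[1])
  } else {
    matrix(0, h, w)  # degenerate all-zero (or flat) map
  }
  structure(list(values = values, target_class = target_class,
                 weights = wts, raw = cam),
            class = "heatmap")
}

# Output of backbone layer `index` for the cached forward pass: re-run the
# prefix (cheap, eval mode, caches already computed are reused implicitly).
activation_at <- function(model, caches, index, images) {
  x <- prep_images(model, images)
  for (i in seq_len(index)) {
    x <- layer_forward(model$groups$backbone[[i]], x, training = FALSE)$out
  }
  x
}

#' Overlay a heatmap on an image
#'
#' The heatmap is rendered through a perceptually uniform colormap and
#' alpha-blended with the image: `alpha = 0` returns the image unchanged,
#' `alpha = 1` the pure colormapped heatmap.
#'
#' @param pixels H x W x 3 integer array (0-255) or a `labeled_image`
#' @param heatmap a `heatmap` or an H x W matrix in `[0, 1]` of matching
#'   spatial size
#' @param alpha blend weight of the heatmap in `[0, 1]`
#' @param palette colormap name passed to [grDevices::hcl.colors()]
#' @return H x W x 3 integer array (0-255)
#' @export
overlay <- function(pixels, heatmap, alpha = 0.4, palette = "viridis") {
  stopifnot(alpha >= 0, alpha <= 1)
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  hm <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!all(dim(pixels)[1:2] == dim(hm))) {
    stop("image and heatmap spatial sizes differ: ",
         paste(dim(pixels)[1:2], collapse = "x"), " vs ",
         paste(dim(hm), collapse = "x"))
  }
  lut <- t(grDevices::col2rgb(grDevices::hcl.colors(256, palette)))
  idx <- pmin(pmax(as.integer(round(hm * 255)) + 1L, 1L), 256L)
  hm_rgb <- array(0, dim = dim(pixels))
  for (ch in 1:3) {
    hm_rgb[, , ch] <- matrix(lut[idx, ch], nrow(hm), ncol(hm))
  }
  out <- (1 - alpha) * pixels + alpha * hm_rgb
  array(as.integer(round(out)), dim = dim(pixels))
}
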