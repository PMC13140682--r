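# Six-stage stochastic augmentation: horizontal flip, rotation, colour
# jitter, random resized crop (back to 128 x 128), random affine
# (rotation + shear), Gaussian noise -- applied in exactly that order.
# All geometric transforms use bilinear interpolation with mirrored
# borders; intensities are clipped to the valid range after each
# photometric stage.

AUG_SIZE <- 128L

#' Construct an augmentation policy
#'
#' Defaults: flip probability 0.5; rotation uniform in +/-30 degrees;
#' brightness/contrast/saturation/hue jitter strength 0.5 each (hue
#' jitter is a shift of up to half the hue half-range, i.e. +/-90
#' degrees); crop area fraction uniform in 0.8 .. 1.0 then resized back to
#' 128 x 128; affine rotation +/-30 degrees with shear up to 10 degrees;
#' Gaussian noise standard deviation 0.05 on [0, 1] intensities.
#'
#' @param flip_prob horizontal-flip probability in `[0, 1]`
#' @param rotation_deg symmetric rotation range, degrees
#' @param jitter_strength named numeric vector with `brightness`,
#'   `contrast`, `saturation`, `hue` maximum relative strengths
#' @param crop_scale length-2 interval of crop area fractions in `(0, 1]`
#' @param affine_rotation_deg symmetric affine rotation range, degrees
#' @param shear_deg maximum shear angle, degrees
#' @param noise_sigma Gaussian noise standard deviation on `[0, 1]`
#' @return an `augmentation_policy` list
#' @export
augmentation_policy <- function(flip_prob = 0.5,
                                rotation_deg = 30,
                                jitter_strength = c(brightness = 0.5,
                                                    contrast = 0.5,
                                                    saturation = 0.5,
                                                    hue = 0.5),
                                crop_scale = c(0.8, 1.0),
                                affine_rotation_deg = 30,
                                shear_deg = 10,
                                noise_sigma = 0.05) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            all(crop_scale > 0), all(crop_scale <= 1),
            crop_scale[1] <= crop_scale[2],
            rotation_deg >= 0, affine_rotation_deg >= 0, shear_deg >= 0,
            noise_sigma >= 0, all(jitter_strength >= 0))
  structure(list(flip_prob = flip_prob, rotation_deg = rotation_deg,
                 jitter_strength = jitter_strength, crop_scale = crop_scale,
                 affine_rotation_deg = affine_rotation_deg,
                 shear_deg = shear_deg, noise_sigma = noise_sigma),
            class = "augmentation_policy")
}

# Rotate about the image centre by `deg`, same output size.
rotate_image <- function(img, deg) {
  if (deg == 0) return(img)
  th <- deg * pi / 180
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  b <- c(cx - A[1, 1] * cx - A[1, 2] * cy, cy - A[2, 1] * cx - A[2, 2] * cy)
  warp_affine(img, A, b, h, w)
}

# Rotation + shear about the centre (shear applied along x).
affine_image <- function(img, deg, shear) {
  if (deg == 0 && shear == 0) return(img)
  th <- deg * pi / 180
  sh <- tan(shear * pi / 180)
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  S <- matrix(c(1, sh, 0, 1), 2, 2, byrow = TRUE)
  A <- R %*% S
  b <- c(cx - A[1, 1] * cx - A[1, 2] * cy, cy - A[2, 1] * cx - A[2, 2] * cy)
  warp_affine(img, A, b, h, w)
}

color_jitter <- function(img, strength, rng_draws) {
  s <- strength
  fb <- 1 + (2 * rng_draws[1] - 1) * s[["brightness"]]
  fc <- 1 + (2 * rng_draws[2] - 1) * s[["contrast"]]
  fs <- 1 + (2 * rng_draws[3] - 1) * s[["saturation"]]
  dh <- (2 * rng_draws[4] - 1) * s[["hue"]] / 2
  img <- clip01(img * fb)
  m <- mean(to_gray(img))
  img <- clip01((img - m) * fc + m)
  g <- to_gray(img)
  for (ch in 1:3) img[, , ch] <- g + fs * (img[, , ch] - g)
  img <- clip01(img)
  if (dh != 0) {
    hsv <- rgb_to_hsv_mat(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]))
    rgb <- hsv_to_rgb((hsv[, "h"] + dh) %% 1, hsv[, "s"], hsv[, "v"])
    img <- array(rgb, dim = dim(img))
  }
  img
}

#' Apply the six-stage augmentation pipeline to one image
#'
#' Transforms are applied in the fixed order flip, rotation, colour
#' jitter, random resized crop, affine, noise; the output is always
#' 128 x 128 x 3 with the label untouched, and a fixed seed reproduces
#' the output bit for bit.
#'
#' @param pixels H x W x 3 integer array (0-255) or a `labeled_image`
#' @param policy an [augmentation_policy()]
#' @param seed integer seed
#' @return 128 x 128 x 3 integer array (0-255)
#' @export
augment <- function(pixels, policy = augmentation_policy(), seed = 1) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  stopifnot(inherits(policy, "augmentation_policy"),
            length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  img <- pixels / 255
  with_seed(seed, {
    # draw all random numbers up front in a fixed order
    u_flip <- runif(1)
    rot <- runif(1, -policy$rotation_deg, policy$rotation_deg)
    jit <- runif(4)
    area <- runif(1, policy$crop_scale[1], policy$crop_scale[2])
    u_cx <- runif(1); u_cy <- runif(1)
    aff_rot <- runif(1, -policy$affine_rotation_deg, policy$affine_rotation_deg)
    shear <- runif(1, 0, policy$shear_deg)
    noise <- if (policy$noise_sigma > 0) {
      array(stats::rnorm(AUG_SIZE * AUG_SIZE * 3, 0, policy$noise_sigma),
            dim = c(AUG_SIZE, AUG_SIZE, 3))
    } else 0

    if (u_flip < policy$flip_prob) img <- img[, rev(seq_len(dim(img)[2])), ]
    img <- rotate_image(img, rot)
    img <- color_jitter(img, policy$jitter_strength, jit)
    # random resized crop: side fraction sqrt(area), random offset, then
    # bilinear resize back to 128 x 128
    h <- dim(img)[1]; w <- dim(img)[2]
    side_h <- max(1L, round(sqrt(area) * h))
    side_w <- max(1L, round(sqrt(area) * w))
    r0 <- 1L + floor(u_cy * (h - side_h + 1))
    c0 <- 1L + floor(u_cx * (w - side_w + 1))
    img <- img[r0:(r0 + side_h - 1L), c0:(c0 + side_w - 1L), , drop = FALSE]
    img <- resize_bilinear(img, AUG_SIZE, AUG_SIZE)
    img <- affine_image(img, aff_rot, shear)
    img <- clip01(img + noise)
  })
  array(as.integer(round(img * 255)), dim = c(AUG_SIZE, AUG_SIZE, 3))
}

#' Generate an augmentation candidate pool
#'
#' Applies the pipeline `per_image` times to every source image; labels
#' are inherited and per-image seeds derived deterministically from the
#' master seed.
#'
#' @param dataset list of `labeled_image`
#' @param per_image candidates generated per source image
#' @param policy an [augmentation_policy()]
#' @param seed integer master seed
#' @return list of `labeled_image` of length `per_image * length(dataset)`
#' @export
generate_pool <- function(dataset, per_image = 1,
                          policy = augmentation_policy(), seed = 1) {
  stopifnot(per_image >= 1)
  if (length(dataset) == 0) stop("empty dataset")
  out <- vector("list", per_image * length(dataset))
  k <- 0L
  for (i in seq_along(dataset)) {
    for (j in seq_len(per_image)) {
      k <- k + 1L
      px <- augment(dataset[[i]], policy,
                    seed = derive_seed(seed, dataset[[i]]$source_id, j))
      out[[k]] <- labeled_image(px, dataset[[i]]$label,
                                sprintf("%s-aug%02d", dataset[[i]]$source_id, j))
    }
  }
  out
}
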