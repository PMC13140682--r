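# Handcrafted feature extraction: eleven descriptor groups computed on
# preprocessed 128 x 128 RGB frames and concatenated into one 34,485-dim
# vector. Group lengths are a hard contract; every extractor returns its
# stated length for any valid input, including constant and pure-noise
# images.

FEATURE_SIZE <- 128L

#' Canonical feature groups and their lengths
#'
#' Concatenation always follows this order: LBP, Haralick, ColorHistogram,
#' DominantColors, EdgeHistogram, HOG, SIFT, ORB, PixelStats, Entropy, DCT.
#'
#' @return named integer vector of per-group output lengths (sums to 34485)
#' @export
feature_groups <- function() {
  c(LBP = 16384L, Haralick = 5L, ColorHistogram = 768L, DominantColors = 9L,
    EdgeHistogram = 256L, HOG = 512L, SIFT = 128L, ORB = 32L,
    PixelStats = 6L, Entropy = 1L, DCT = 16384L)
}

#' Resize to 128 x 128 and scale intensities to [0, 1]
#'
#' Bilinear resampling; a 128 x 128 input is only rescaled in intensity.
#'
#' @param pixels H x W x 3 integer array (0-255) or a `labeled_image`
#' @return 128 x 128 x 3 double array in `[0, 1]`
#' @export
preprocess_for_features <- function(pixels) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1) {
    stop("expected a non-empty H x W x 3 pixel array")
  }
  img <- pixels / 255
  if (d[1] != FEATURE_SIZE || d[2] != FEATURE_SIZE) {
    img <- resize_bilinear(img, FEATURE_SIZE, FEATURE_SIZE)
  }
  img
}

# 0-255 integer gray levels used by histogram-type descriptors.
gray_levels <- function(img) {
  matrix(as.integer(round(to_gray(img) * 255)), nrow(img[, , 1]))
}

## ---- LBP -------------------------------------------------------------

# 8-neighbour, radius-1 local binary pattern code map on the grayscale
# image (replicated border), flattened column-major: 128 * 128 = 16384.
lbp_features <- function(img) {
  g <- to_gray(img)
  h <- nrow(g); w <- ncol(g)
  gp <- g[c(1, seq_len(h), h), c(1, seq_len(w), w)]  # replicate pad
  ctr <- gp[2:(h + 1), 2:(w + 1)]
  # neighbours clockwise from east, weights 2^0 .. 2^7
  shifts <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                 c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  code <- matrix(0, h, w)
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    nb <- gp[2:(h + 1) + dr, 2:(w + 1) + dc]
    code <- code + 2^(k - 1) * (nb >= ctr)
  }
  as.vector(code)
}

## ---- Haralick --------------------------------------------------------

# Five GLCM texture statistics (contrast, dissimilarity, homogeneity,
# energy, correlation) from a single symmetric normalized co-occurrence
# matrix: 256 gray levels, offset (0, 1).
haralick_features <- function(img) {
  gl <- gray_levels(img)
  a <- gl[, -ncol(gl)]
  b <- gl[, -1]
  idx <- as.vector(a) * 256L + as.vector(b) + 1L
  cnt <- tabulate(idx, nbins = 65536L)
  G <- matrix(cnt, 256, 256, byrow = TRUE)  # row = first level
  G <- G + t(G)
  P <- G / sum(G)
  lv <- 0:255
  diffm <- outer(lv, lv, "-")
  contrast <- sum(P * diffm^2)
  dissimilarity <- sum(P * abs(diffm))
  homogeneity <- sum(P / (1 + diffm^2))
  asm <- sum(P^2)
  energy <- sqrt(asm)
  pi_m <- rowSums(P)
  mu <- sum(lv * pi_m)
  sdv <- sqrt(sum((lv - mu)^2 * pi_m))
  correlation <- if (sdv > 0) {
    (sum(outer(lv, lv) * P) - mu^2) / sdv^2
  } else 0
  c(contrast, dissimilarity, homogeneity, energy, correlation)
}

## ---- Colour histogram ------------------------------------------------

# 256 bins per RGB channel, concatenated R, G, B: length 768. Raw counts by
# default (each channel sums to the pixel count); `counts = FALSE` gives
# frequencies.
color_histogram <- function(img, counts = TRUE) {
  out <- unlist(lapply(1:3, function(ch) {
    v <- as.integer(round(img[, , ch] * 255))
    tabulate(v + 1L, nbins = 256L)
  }))
  if (!counts) out <- out / (dim(img)[1] * dim(img)[2])
  as.numeric(out)
}

## ---- Dominant colours ------------------------------------------------

# k-means (k = 3) RGB centroids sorted by cluster population descending,
# flattened centroid-by-centroid: length 9. A degenerate image with fewer
# than 3 distinct colours repeats the mean colour.
dominant_colors <- function(img, seed = 1) {
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  uq <- unique(px)
  if (nrow(uq) < 3) {
    ctr <- colMeans(px)
    return(rep(ctr, 3))
  }
  # fixed iteration budget; a non-converged warning is irrelevant here
  # because only the (deterministic, seeded) centroids are consumed
  km <- with_seed(derive_seed(seed, "dominant-colors"),
                  suppressWarnings(
                    stats::kmeans(px, centers = 3, iter.max = 50,
                                  nstart = 1, algorithm = "Lloyd")))
  ord <- order(km$size, decreasing = TRUE)
  as.vector(t(km$centers[ord, , drop = FALSE]))
}

## ---- Canny edge histogram -------------------------------------------

# Canny edge map (Gaussian sigma 1.4, Sobel, non-maximum suppression,
# hysteresis with thresholds 100/200 on the 0-255 gradient magnitude);
# the feature is the 256-bin histogram of grayscale intensity values at
# edge pixels.
canny_edges <- function(g255, low = 100, high = 200) {
  g <- gaussian_blur(g255, 1.4)
  h <- nrow(g); w <- ncol(g)
  shift <- function(m, dr, dc) {
    m[reflect_index(seq_len(h) + dr, h), reflect_index(seq_len(w) + dc, w)]
  }
  gx <- (shift(g, 0, 1) - shift(g, 0, -1)) +
    0.5 * (shift(g, -1, 1) - shift(g, -1, -1) +
           shift(g, 1, 1) - shift(g, 1, -1))
  gy <- (shift(g, 1, 0) - shift(g, -1, 0)) +
    0.5 * (shift(g, 1, -1) - shift(g, -1, -1) +
           shift(g, 1, 1) - shift(g, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4)) %% 4  # 0=E,1=SE,2=S,3=SW
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0, 1), "1" = c(1, 1), "2" = c(1, 0), "3" = c(1, -1))
    sel <- sector == s
    n1[sel] <- shift(mag, d[1], d[2])[sel]
    n2[sel] <- shift(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low & mag < high
  # hysteresis: grow strong edges into connected weak pixels
  repeat {
    nb <- shift(strong, 0, 1) | shift(strong, 0, -1) |
      shift(strong, 1, 0) | shift(strong, -1, 0) |
      shift(strong, 1, 1) | shift(strong, 1, -1) |
      shift(strong, -1, 1) | shift(strong, -1, -1)
    add <- weak & nb & !strong
    if (!any(add)) break
    strong <- strong | add
  }
  strong
}

edge_histogram <- function(img, counts = TRUE) {
  gl <- gray_levels(img)
  edges <- canny_edges(gl)
  hist <- tabulate(gl[edges] + 1L, nbins = 256L)
  if (!counts && sum(hist) > 0) hist <- hist / sum(hist)
  as.numeric(hist)
}

## ---- HOG -------------------------------------------------------------

# Oriented-gradient histogram on the grayscale image: 8 unsigned
# orientation bins, 16 x 16 pixel cells over the 128 x 128 frame, no block
# normalisation -> 8 x 8 cells x 8 bins = 512 values.
hog_features <- function(img) {
  g <- to_gray(img)
  h <- nrow(g); w <- ncol(g)
  shift <- function(m, dr, dc) {
    m[reflect_index(seq_len(h) + dr, h), reflect_index(seq_len(w) + dc, w)]
  }
  gx <- (shift(g, 0, 1) - shift(g, 0, -1)) / 2
  gy <- (shift(g, 1, 0) - shift(g, -1, 0)) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  bin <- pmin(floor(ang / (pi / 8)), 7)
  cell_r <- (seq_len(h) - 1) %/% 16
  cell_c <- (seq_len(w) - 1) %/% 16
  cr <- matrix(cell_r, h, w)
  cc <- matrix(cell_c, h, w, byrow = TRUE)
  group <- bin + 8 * cr + 64 * cc + 1
  out <- numeric(512)
  agg <- rowsum(as.vector(mag), group = as.vector(group))
  out[as.integer(rownames(agg))] <- agg
  out
}

## ---- SIFT-style descriptors -----------------------------------------

# Difference-of-Gaussians keypoints with rotation-normalised 4 x 4 x 8
# gradient-orientation descriptors (unit-normalised, 0.2-clipped,
# renormalised), averaged over detected keypoints: length 128. An image
# with no keypoints yields the zero vector.
sift_features <- function(img, max_keypoints = 40L) {
  g <- to_gray(img)
  h <- nrow(g); w <- ncol(g)
  b1 <- gaussian_blur(g, 1.0)
  b2 <- gaussian_blur(g, 1.6)
  dog <- b2 - b1
  border <- 10L
  inner <- dog[(border + 1):(h - border), (border + 1):(w - border)]
  thr <- 0.004
  # strict local extrema of the DoG response in a 3 x 3 neighbourhood
  nh <- nrow(inner); nw <- ncol(inner)
  is_max <- matrix(TRUE, nh, nw); is_min <- matrix(TRUE, nh, nw)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbv <- dog[(border + 1 + dr):(h - border + dr),
               (border + 1 + dc):(w - border + dc)]
    is_max <- is_max & (inner > nbv)
    is_min <- is_min & (inner < nbv)
  }
  cand <- which((is_max | is_min) & abs(inner) > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(numeric(128))
  resp <- abs(inner[cand])
  ord <- order(resp, decreasing = TRUE)
  cand <- cand[ord[seq_len(min(max_keypoints, nrow(cand)))], , drop = FALSE]
  kps <- cbind(cand[, 1] + border, cand[, 2] + border)  # (row, col)

  gxm <- (b1[, c(2:w, w)] - b1[, c(1, 1:(w - 1))]) / 2
  gym <- (b1[c(2:h, h), ] - b1[c(1, 1:(h - 1)), ]) / 2
  magm <- sqrt(gxm^2 + gym^2)
  angm <- atan2(gym, gxm)

  desc_sum <- numeric(128)
  n_ok <- 0L
  for (ki in seq_len(nrow(kps))) {
    r0 <- kps[ki, 1]; c0 <- kps[ki, 2]
    # dominant orientation from a 36-bin weighted histogram
    rr <- pmax(1, r0 - 7):pmin(h, r0 + 8)
    cc <- pmax(1, c0 - 7):pmin(w, c0 + 8)
    ob <- floor(((angm[rr, cc] %% (2 * pi)) / (2 * pi)) * 36) %% 36
    ohist <- numeric(36)
    agg <- rowsum(as.vector(magm[rr, cc]), as.vector(ob) + 1)
    ohist[as.integer(rownames(agg))] <- agg
    theta <- (which.max(ohist) - 0.5) * 2 * pi / 36
    ct <- cos(theta); st <- sin(theta)
    # 16 x 16 rotated sampling grid, 1px spacing, centred on the keypoint
    u <- rep(seq(-7.5, 7.5, length.out = 16), times = 16)
    v <- rep(seq(-7.5, 7.5, length.out = 16), each = 16)
    xs <- c0 + u * ct - v * st
    ys <- r0 + u * st + v * ct
    m <- bilinear_sample(array(magm, dim = c(h, w, 1)), ys, xs)[, 1]
    a <- bilinear_sample(array(angm, dim = c(h, w, 1)), ys, xs)[, 1]
    rel <- (a - theta) %% (2 * pi)
    obin <- floor(rel / (pi / 4)) %% 8
    cellx <- pmin((u + 8) %/% 4, 3)
    celly <- pmin((v + 8) %/% 4, 3)
    wgt <- m * exp(-(u^2 + v^2) / (2 * 8^2))
    group <- obin + 8 * cellx + 32 * celly + 1
    d <- numeric(128)
    agg <- rowsum(wgt, group)
    d[as.integer(rownames(agg))] <- agg
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    d <- pmin(d / nrm, 0.2)
    d <- d / sqrt(sum(d^2))
    desc_sum <- desc_sum + d
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) return(numeric(128))
  desc_sum / n_ok
}

## ---- ORB-style descriptors ------------------------------------------

# Fixed pattern of 256 intensity-comparison point pairs used by the binary
# descriptor; generated once from an internal constant seed.
orb_pattern <- local({
  pat <- NULL
  function() {
    if (is.null(pat)) {
      pat <<- with_seed(880714L, {
        p <- matrix(round(pmin(pmax(stats::rnorm(256 * 4, 0, 6.2), -14), 14)),
                    256, 4)
        colnames(p) <- c("x1", "y1", "x2", "y2")
        p
      })
    }
    pat
  }
})

# FAST-like corners (16-pixel Bresenham circle, 9 contiguous brighter or
# darker) with intensity-centroid orientation and a steered 256-bit binary
# descriptor packed into 32 bytes, averaged over keypoints.
orb_features <- function(img, max_keypoints = 40L, threshold = 0.07) {
  g <- gaussian_blur(to_gray(img), 1.0)
  h <- nrow(g); w <- ncol(g)
  circ <- matrix(c(0, 3, 1, 3, 2, 2, 3, 1, 3, 0, 3, -1, 2, -2, 1, -3,
                   0, -3, -1, -3, -2, -2, -3, -1, -3, 0, -3, 1, -2, 2, -1, 3),
                 ncol = 2, byrow = TRUE)  # (dy, dx)? stored as (dr, dc)
  border <- 17L
  rs <- (border + 1):(h - border)
  cs <- (border + 1):(w - border)
  ctr <- g[rs, cs]
  brighter <- array(FALSE, c(length(rs), length(cs), 16))
  darker <- array(FALSE, c(length(rs), length(cs), 16))
  for (k in 1:16) {
    nb <- g[rs + circ[k, 1], cs + circ[k, 2]]
    brighter[, , k] <- nb > ctr + threshold
    darker[, , k] <- nb < ctr - threshold
  }
  run_of <- function(flags) {
    ok <- matrix(FALSE, length(rs), length(cs))
    for (s in 0:15) {
      all9 <- flags[, , (s %% 16) + 1]
      for (j in 1:8) all9 <- all9 & flags[, , ((s + j) %% 16) + 1]
      ok <- ok | all9
    }
    ok
  }
  corner <- run_of(brighter) | run_of(darker)
  if (!any(corner)) return(numeric(32))
  # corner score: summed absolute contrast on the circle; 3 x 3 NMS
  score <- matrix(0, length(rs), length(cs))
  for (k in 1:16) {
    score <- score + abs(g[rs + circ[k, 1], cs + circ[k, 2]] - ctr)
  }
  score[!corner] <- 0
  nh <- nrow(score); nw <- ncol(score)
  is_peak <- score > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- score[reflect_index(seq_len(nh) + dr, nh),
                     reflect_index(seq_len(nw) + dc, nw)]
    is_peak <- is_peak & (score >= shifted)
  }
  peaks <- which(is_peak, arr.ind = TRUE)
  ord <- order(score[peaks], decreasing = TRUE)
  peaks <- peaks[ord[seq_len(min(max_keypoints, nrow(peaks)))], , drop = FALSE]
  pat <- orb_pattern()
  desc_sum <- numeric(32)
  for (ki in seq_len(nrow(peaks))) {
    r0 <- peaks[ki, 1] + border; c0 <- peaks[ki, 2] + border
    # intensity-centroid orientation in a 15-px square patch
    rr <- (r0 - 7):(r0 + 7); cc <- (c0 - 7):(c0 + 7)
    patch <- g[rr, cc]
    ys <- rep(-7:7, times = 15); xs <- rep(-7:7, each = 15)
    m01 <- sum(ys * patch); m10 <- sum(xs * patch)
    th <- atan2(m01, m10)
    ct <- cos(th); st <- sin(th)
    x1 <- c0 + round(pat[, "x1"] * ct - pat[, "y1"] * st)
    y1 <- r0 + round(pat[, "x1"] * st + pat[, "y1"] * ct)
    x2 <- c0 + round(pat[, "x2"] * ct - pat[, "y2"] * st)
    y2 <- r0 + round(pat[, "x2"] * st + pat[, "y2"] * ct)
    x1 <- pmin(pmax(x1, 1), w); y1 <- pmin(pmax(y1, 1), h)
    x2 <- pmin(pmax(x2, 1), w); y2 <- pmin(pmax(y2, 1), h)
    bits <- g[cbind(y1, x1)] < g[cbind(y2, x2)]
    bytes <- colSums(matrix(bits, 8, 32) * 2^(0:7))
    desc_sum <- desc_sum + bytes
  }
  desc_sum / nrow(peaks)
}

## ---- Simple statistics ----------------------------------------------

# Per-channel means then per-channel standard deviations: length 6.
pixel_stats <- function(img) {
  mns <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  sds <- vapply(1:3, function(ch) stats::sd(as.vector(img[, , ch])),
                numeric(1))
  c(mns, sds)
}

# Shannon entropy (base 2) of the 256-bin grayscale intensity histogram.
shannon_entropy <- function(img) {
  p <- tabulate(as.vector(gray_levels(img)) + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## ---- DCT -------------------------------------------------------------

# Type-II discrete cosine transform of the grayscale image, the plain
# X(u, v) = sum_m sum_n g(m, n) cos(pi (2m+1) u / 2M) cos(pi (2n+1) v / 2N)
# definition without scale factors; coefficients flattened column-major.
dct2 <- function(g) {
  n <- nrow(g)
  m <- ncol(g)
  Cn <- cos(pi * outer(0:(n - 1), 2 * (0:(n - 1)) + 1) / (2 * n))
  Cm <- cos(pi * outer(0:(m - 1), 2 * (0:(m - 1)) + 1) / (2 * m))
  Cn %*% g %*% t(Cm)
}

dct_features <- function(img) {
  as.vector(dct2(to_gray(img)))
}

## ---- Dispatch --------------------------------------------------------

#' Extract one handcrafted feature group
#'
#' @param img preprocessed image from [preprocess_for_features()]
#' @param group one of `names(feature_groups())`
#' @param seed integer seed; only the DominantColors k-means initialisation
#'   consumes it
#' @param counts use raw counts (`TRUE`, default) or frequencies for the
#'   histogram-type groups
#' @return numeric vector of the group's contracted length
#' @export
extract_group <- function(img, group, seed = 1, counts = TRUE) {
  stopifnot(length(dim(img)) == 3,
            dim(img)[1] == FEATURE_SIZE, dim(img)[2] == FEATURE_SIZE)
  out <- switch(group,
    LBP = lbp_features(img),
    Haralick = haralick_features(img),
    ColorHistogram = color_histogram(img, counts),
    DominantColors = dominant_colors(img, seed),
    EdgeHistogram = edge_histogram(img, counts),
    HOG = hog_features(img),
    SIFT = sift_features(img),
    ORB = orb_features(img),
    PixelStats = pixel_stats(img),
    Entropy = shannon_entropy(img),
    DCT = dct_features(img),
    stop("unknown feature group: ", group)
  )
  stopifnot(length(out) == feature_groups()[[group]], all(is.finite(out)))
  out
}

#' Extract all feature groups into one concatenated vector
#'
#' @inheritParams extract_group
#' @return a `feature_vector`: list with `values` (length 34485) and
#'   `layout`, a data frame of per-group offsets and lengths
#' @export
extract_all <- function(img, seed = 1, counts = TRUE) {
  sizes <- feature_groups()
  vals <- unlist(lapply(names(sizes), function(g) {
    extract_group(img, g, seed = seed, counts = counts)
  }), use.names = FALSE)
  offsets <- cumsum(c(0L, unname(sizes[-length(sizes)])))
  structure(list(values = vals,
                 layout = data.frame(group = names(sizes),
                                     offset = offsets,
                                     length = unname(sizes))),
            class = "feature_vector")
}

#' Extract the feature table for a whole dataset
#'
#' @param dataset list of `labeled_image`
#' @param seed integer seed (per-image sub-seeds are derived from it)
#' @param counts raw counts vs frequencies for histogram groups
#' @return numeric matrix, one row per image, with a `labels` attribute
#'   holding the class labels and `layout` the group layout
#' @export
extract_features <- function(dataset, seed = 1, counts = TRUE) {
  stopifnot(length(dataset) >= 1)
  first <- extract_all(preprocess_for_features(dataset[[1]]),
                       seed = derive_seed(seed, dataset[[1]]$source_id),
                       counts = counts)
  X <- matrix(0, length(dataset), length(first$values))
  X[1, ] <- first$values
  if (length(dataset) > 1) {
    for (i in 2:length(dataset)) {
      X[i, ] <- extract_all(preprocess_for_features(dataset[[i]]),
                            seed = derive_seed(seed, dataset[[i]]$source_id),
                            counts = counts)$values
    }
  }
  attr(X, "labels") <- dataset_labels(dataset)
  attr(X, "layout") <- first$layout
  X
}
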