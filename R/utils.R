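# Shared helpers: seeding, RNG scoping, bilinear warps, colour conversions.

#' Derive a reproducible sub-seed from a master seed and string tags
#'
#' All stochastic stages take one integer seed; sub-seeds for nested draws
#' (per image, per generation, per individual) are derived with a small
#' multiplicative hash so that evaluation order never changes results.
#'
#' @param seed master integer seed
#' @param ... further character or integer tags identifying the consumer
#' @return an integer in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    for (cp in utf8ToInt(tag)) {
      h <- (h * 69069 + cp) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Reflect 1-based indices into [1, n] (mirror boundary, edge pixels not
# repeated twice unless n == 1).
reflect_index <- function(i, n) {
  if (n == 1L) {
    return(rep(1L, length(i)))
  }
  period <- 2L * n - 2L
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  j <- pmin(j, period - j)
  as.integer(j + 1L)
}

# Bilinear sampling of an H x W x C array at fractional (row, col)
# coordinates (1-based), with mirrored borders. xs/ys are vectors of equal
# length; returns length(xs) x C matrix.
bilinear_sample <- function(img, ys, xs) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  r0 <- reflect_index(as.integer(y0), h)
  r1 <- reflect_index(as.integer(y0) + 1L, h)
  c0 <- reflect_index(as.integer(x0), w)
  c1 <- reflect_index(as.integer(x0) + 1L, w)
  out <- matrix(0, length(xs), nc)
  plane <- h * w
  for (ch in seq_len(nc)) {
    off <- (ch - 1L) * plane
    v00 <- img[off + r0 + (c0 - 1L) * h]
    v01 <- img[off + r0 + (c1 - 1L) * h]
    v10 <- img[off + r1 + (c0 - 1L) * h]
    v11 <- img[off + r1 + (c1 - 1L) * h]
    out[, ch] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  out
}

# Apply the inverse affine map (A, b): output pixel (r, c) samples input at
# A %*% (c, r) + b in (x = col, y = row) coordinates. img: H x W x C in [0,1].
warp_affine <- function(img, A, b, out_h, out_w) {
  grid_c <- rep(seq_len(out_w), each = out_h)
  grid_r <- rep(seq_len(out_h), times = out_w)
  xs <- A[1, 1] * grid_c + A[1, 2] * grid_r + b[1]
  ys <- A[2, 1] * grid_c + A[2, 2] * grid_r + b[2]
  v <- bilinear_sample(img, ys, xs)
  array(v, dim = c(out_h, out_w, dim(img)[3]))
}

# Bilinear resize with pixel-centre alignment.
resize_bilinear <- function(img, out_h, out_w) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sy <- h / out_h; sx <- w / out_w
  # output centre (i - 0.5) maps to input (i - 0.5) * s, kept 1-based
  grid_c <- rep(seq_len(out_w), each = out_h)
  grid_r <- rep(seq_len(out_h), times = out_w)
  xs <- (grid_c - 0.5) * sx + 0.5
  ys <- (grid_r - 0.5) * sy + 0.5
  v <- bilinear_sample(img, ys, xs)
  array(v, dim = c(out_h, out_w, dim(img)[3]))
}

# ITU-R 601 luma of an H x W x 3 array in [0,1].
to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Vectorised HSV (h in [0,1)) -> RGB, all components in [0,1].
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Vectorised RGB -> HSV on matrices of equal length vectors; h in [0,1).
rgb_to_hsv_mat <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(h = h, s = s, v = mx)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur of a matrix (single channel).
gaussian_blur <- function(m, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  pad <- function(idx, n) reflect_index(idx, n)
  out <- matrix(0, h, w)
  for (d in seq_along(k)) {
    out <- out + k[d] * m[pad(seq_len(h) + d - radius - 1L, h), , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (d in seq_along(k)) {
    out2 <- out2 + k[d] * out[, pad(seq_len(w) + d - radius - 1L, w), drop = FALSE]
  }
  out2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
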