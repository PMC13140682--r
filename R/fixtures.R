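# Synthetic four-class image fixtures, dataset splitting and PNG / manifest
# I/O. Classes are separable by a chromatic signature (dominant hue band)
# plus a sinusoidal texture frequency, the statistics the handcrafted
# feature groups respond to.

#' The four tissue class labels
#'
#' High-Grade Cancer, Low-Grade Cancer, Non-Suspicious Tissue and No Tumor
#' Lesion, in canonical order. Integer encodings used elsewhere are
#' 0-based positions into this vector.
#'
#' @return character vector of length 4
#' @export
class_labels <- function() c("HGC", "LGC", "NST", "NTL")

#' Construct a class signature for the synthetic generator
#'
#' @param hue_center dominant hue, degrees on the colour wheel
#' @param texture_frequency sinusoidal texture frequency, cycles per image
#'   width
#' @param noise_sigma Gaussian pixel noise standard deviation as a fraction
#'   of the intensity range; must be non-negative
#' @return a `class_signature` list
#' @export
class_signature <- function(hue_center, texture_frequency, noise_sigma = 0.03) {
  stopifnot(noise_sigma >= 0)
  structure(list(hue_center = hue_center,
                 texture_frequency = texture_frequency,
                 noise_sigma = noise_sigma),
            class = "class_signature")
}

#' Default class signatures
#'
#' Hue centres 90 degrees apart and distinct texture frequencies give four
#' classes that colour-histogram, texture and frequency-domain descriptors
#' separate cleanly.
#'
#' @return named list of four `class_signature` objects
#' @export
default_signatures <- function() {
  list(
    HGC = class_signature(0,   3, 0.03),
    LGC = class_signature(90,  6, 0.03),
    NST = class_signature(180, 10, 0.03),
    NTL = class_signature(270, 16, 0.03)
  )
}

#' Construct a labeled image
#'
#' @param pixels H x W x 3 integer array, values 0-255, RGB channel order
#' @param label one of [class_labels()]
#' @param source_id opaque string identifying the image origin
#' @return a `labeled_image` list
#' @export
labeled_image <- function(pixels, label, source_id) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            min(pixels) >= 0, max(pixels) <= 255,
            label %in% class_labels())
  structure(list(pixels = pixels, label = label, source_id = source_id),
            class = "labeled_image")
}

# Render one synthetic frame for a signature. Deterministic in (signature,
# size, seed).
synth_image <- function(signature, size, seed) {
  with_seed(seed, {
    n <- size * size
    xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
    ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index
    f <- signature$texture_frequency
    phase1 <- runif(1, 0, 2 * pi)
    phase2 <- runif(1, 0, 2 * pi)
    tex <- 0.5 * sin(2 * pi * f * xs / size + phase1) +
           0.5 * sin(2 * pi * f * ys / size + phase2)
    # smooth illumination gradient, a mild nuisance factor
    gdir <- runif(1, 0, 2 * pi)
    grad <- 0.08 * ((xs / size) * cos(gdir) + (ys / size) * sin(gdir))
    hue <- (signature$hue_center / 360 +
            0.02 * matrix(rnorm(n), size, size)) %% 1
    sat <- clip01(0.62 + 0.12 * tex)
    val <- clip01(0.55 + 0.22 * tex + grad)
    rgb <- hsv_to_rgb(as.vector(hue), as.vector(sat), as.vector(val))
    rgb <- rgb + signature$noise_sigma * matrix(rnorm(3 * n), n, 3)
    px <- array(as.integer(round(clip01(rgb) * 255)), dim = c(size, size, 3))
    px
  })
}

#' Generate a seeded synthetic four-class dataset
#'
#' Produces `n_per_class` images per class whose dominant hue and texture
#' band follow each class signature. Identical seeds yield bit-identical
#' pixels.
#'
#' @param n_per_class images per class, at least 1
#' @param signatures named list of four signatures, one per class; hue
#'   centres must be pairwise distinct
#' @param size image side in pixels, at least 32
#' @param seed integer master seed
#' @return list of `labeled_image`, classes interleaved in label order
#' @export
generate_synthetic_dataset <- function(n_per_class,
                                       signatures = default_signatures(),
                                       size = 128, seed = 1) {
  stopifnot(n_per_class >= 1, size >= 32)
  labels <- class_labels()
  stopifnot(all(labels %in% names(signatures)))
  hues <- vapply(signatures[labels], function(s) s$hue_center, numeric(1))
  if (anyDuplicated(hues %% 360)) {
    stop("class signatures must have pairwise distinct hue centers")
  }
  out <- vector("list", 4L * n_per_class)
  k <- 0L
  for (i in seq_len(n_per_class)) {
    for (lab in labels) {
      k <- k + 1L
      sid <- sprintf("synth-%s-%04d", lab, i)
      px <- synth_image(signatures[[lab]], size, derive_seed(seed, sid))
      out[[k]] <- labeled_image(px, lab, sid)
    }
  }
  out
}

#' Class labels of a dataset
#' @param dataset list of `labeled_image`
#' @return character vector of labels
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(im) im$label, character(1))
}

#' Source identifiers of a dataset
#' @param dataset list of `labeled_image`
#' @return character vector of source ids
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset, function(im) im$source_id, character(1))
}

# Largest-remainder apportionment of `total` across classes proportional to
# `counts`.
apportion <- function(counts, fraction) {
  total <- round(sum(counts) * fraction)
  raw <- counts * fraction
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_idx <- order(raw - base)
    take <- order_idx[seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' The dataset is first split into a held-out test fraction, then the
#' remainder into training and validation. Both splits are stratified by
#' class with largest-remainder apportionment of per-class counts, so
#' per-class proportions are honoured to within one image.
#'
#' @param dataset list of `labeled_image`
#' @param test_fraction fraction held out as the test set (default 0.1)
#' @param val_fraction fraction of the remainder assigned to validation
#'   (default 0.2)
#' @param seed integer seed controlling the random assignment
#' @param by_patient if `TRUE`, stratified sampling operates on patient
#'   groups (the `source_id` prefix before the last `-`) rather than single
#'   images, preventing one source from spanning splits
#' @return a `dataset_split` list with `train`, `validation`, `test`
#' @export
stratified_split <- function(dataset, test_fraction = 0.1,
                             val_fraction = 0.2, seed = 1,
                             by_patient = FALSE) {
  labels <- dataset_labels(dataset)
  counts <- table(factor(labels, levels = class_labels()))
  present <- names(counts)[counts > 0]
  if (any(counts[present] < 3) && (test_fraction > 0 && val_fraction > 0)) {
    stop("degenerate stratification: every class needs at least 3 members")
  }
  units <- seq_along(dataset)
  groups <- if (by_patient) sub("-[^-]*$", "", dataset_ids(dataset)) else
    dataset_ids(dataset)

  class_n <- as.integer(counts[present])
  n_test <- apportion(class_n, test_fraction)
  n_val <- apportion(class_n - n_test, val_fraction)

  assign_split <- with_seed(derive_seed(seed, "split"), {
    test_idx <- integer(0)
    val_idx <- integer(0)
    for (ci in seq_along(present)) {
      idx <- units[labels == present[ci]]
      idx <- idx[order(groups[idx])]   # stable under input permutation
      idx <- idx[sample.int(length(idx))]
      te <- idx[seq_len(n_test[ci])]
      rest <- idx[-seq_len(n_test[ci])]
      if (n_test[ci] == 0) rest <- idx
      va <- rest[seq_len(n_val[ci])]
      if (n_val[ci] == 0) va <- integer(0)
      test_idx <- c(test_idx, te)
      val_idx <- c(val_idx, va)
    }
    list(test = test_idx, val = val_idx)
  })
  test_idx <- assign_split$test
  val_idx <- assign_split$val
  train_idx <- setdiff(units, c(test_idx, val_idx))
  structure(list(train = dataset[train_idx],
                 validation = dataset[val_idx],
                 test = dataset[test_idx]),
            class = "dataset_split")
}

#' Compose the derived dataset sets from a split and a selected pool
#'
#' Returns the standard compositions: `Training`, `Validation`, `Test`,
#' `D1` (the selected augmented images), `D2` = Training + D1, `D3` =
#' Training + Validation, and `D4` = Training + Validation + D1.
#'
#' @param split a `dataset_split`
#' @param d1 list of `labeled_image` selected from the augmentation pool
#'   (may be empty)
#' @return named list of image lists
#' @export
dataset_compositions <- function(split, d1 = list()) {
  list(Training = split$train,
       Validation = split$validation,
       Test = split$test,
       D1 = d1,
       D2 = c(split$train, d1),
       D3 = c(split$train, split$validation),
       D4 = c(split$train, split$validation, d1))
}

#' Read an 8-bit PNG as a labeled image
#'
#' Grayscale or RGBA inputs are converted to RGB with a warning.
#'
#' @param path PNG file path
#' @param label optional class label; `NA` gives an unlabeled pixel read
#' @param source_id identifier recorded on the image (defaults to the file
#'   name)
#' @return a `labeled_image` (label `NA` allowed for raw reads)
#' @export
read_image_png <- function(path, label = NA_character_,
                           source_id = basename(path)) {
  raw <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot parse PNG '", path, "': ", conditionMessage(e))
  })
  if (length(dim(raw)) == 2) {
    warning("grayscale PNG converted to RGB: ", path)
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  } else if (dim(raw)[3] == 2) {
    warning("gray+alpha PNG converted to RGB: ", path)
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  } else if (dim(raw)[3] == 4) {
    warning("RGBA PNG converted to RGB (alpha dropped): ", path)
    raw <- raw[, , 1:3]
  }
  px <- array(as.integer(round(raw * 255)), dim = dim(raw))
  if (is.na(label)) {
    structure(list(pixels = px, label = NA_character_, source_id = source_id),
              class = "labeled_image")
  } else {
    labeled_image(px, label, source_id)
  }
}

#' Write pixels (or a labeled image) to an 8-bit PNG
#'
#' The write-then-read round trip is lossless for 8-bit RGB.
#'
#' @param image a `labeled_image` or an H x W x 3 integer array (0-255)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_image_png <- function(image, path) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write a dataset manifest and its images
#'
#' The manifest is the plain-text exchange format between stages: one line
#' per image with the relative PNG path, label, source id and split name,
#' tab separated.
#'
#' @param dataset list of `labeled_image`
#' @param dir directory receiving the PNG files
#' @param path manifest file path
#' @param split_name split tag recorded for every image
#' @return `path`, invisibly
#' @export
write_manifest <- function(dataset, dir, path, split_name = "all") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # record paths relative to the manifest's own directory so the manifest
  # plus image tree relocate together
  base <- normalizePath(dirname(path))
  img_dir <- normalizePath(dir)
  prefix <- if (img_dir == base) "" else {
    if (!startsWith(img_dir, paste0(base, "/"))) {
      stop("image directory must sit under the manifest directory")
    }
    paste0(substring(img_dir, nchar(base) + 2L), "/")
  }
  rows <- vapply(dataset, function(im) {
    fname <- paste0(im$source_id, ".png")
    write_image_png(im, file.path(dir, fname))
    paste(paste0(prefix, fname), im$label, im$source_id, split_name,
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a dataset manifest back into labeled images
#'
#' @param path manifest file written by [write_manifest()]
#' @param dir directory holding the PNGs (defaults to the manifest's)
#' @return list of `labeled_image`
#' @export
read_manifest <- function(path, dir = dirname(path)) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  lapply(rows, function(r) {
    read_image_png(file.path(dir, r[[1]]), label = r[[2]], source_id = r[[3]])
  })
}
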