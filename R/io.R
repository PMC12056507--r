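# Image and manifest I/O, bit-depth conversion, resizing, dataset
# splitting and training-time augmentation.

#' Gray-scale image container
#'
#' A 2-D intensity raster with its bit depth and physical pixel size.
#' Values are stored as a numeric matrix indexed [row, col] in native
#' integer units (0..255 or 0..65535).
#'
#' @param values numeric matrix.
#' @param bit_depth 8 or 16.
#' @param pixel_size physical size of one pixel in micrometers
#'   (default 2.04 um/px, a typical brightfield setup).
#' @return Object of class `gray_image`.
#' @export
gray_image <- function(values, bit_depth = 16, pixel_size = 2.04) {
  stopifnot(is.matrix(values), bit_depth %in% c(8, 16), pixel_size > 0)
  if (min(values) < 0 || max(values) > 2^bit_depth - 1)
    stop("values exceed the ", bit_depth, "-bit range")
  structure(list(values = values, bit_depth = as.integer(bit_depth),
                 pixel_size = pixel_size), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d px, %d-bit, %.3g um/px\n",
              nrow(x$values), ncol(x$values), x$bit_depth, x$pixel_size))
  invisible(x)
}

#' Convert a 16-bit image to 8-bit by per-image min-max rescaling
#'
#' The smallest gray value of the image is mapped to 0 and the largest
#' to 255, with round-half-up; this preserves contrast even when the
#' acquisition uses only a narrow band of the 16-bit range.  A constant
#' image (max = min) maps to all zeros.  8-bit input passes through
#' unchanged.
#'
#' @param image a `gray_image`.
#' @return An 8-bit `gray_image`.
#' @export
to_8bit <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  if (image$bit_depth == 8L) return(image)
  v <- image$values
  lo <- min(v); hi <- max(v)
  out <- if (hi > lo) round_half_up((v - lo) * (255 / (hi - lo)))
         else matrix(0, nrow(v), ncol(v))
  gray_image(out, bit_depth = 8, pixel_size = image$pixel_size)
}

#' Resize an image, mask or probability map
#'
#' Images and probability maps are resampled with bilinear
#' interpolation, masks with nearest-neighbour so they stay binary.
#' Output dimensions are `round(dim * factor)`.
#'
#' @param x `gray_image`, logical mask matrix, or numeric matrix.
#' @param factor scale factor in (0, 1] for downscaling or > 1 for
#'   upscaling.
#' @param kind `"auto"` (masks by type), `"bilinear"` or `"nearest"`.
#' @return Same kind of object at the new size.
#' @export
resize <- function(x, factor, kind = c("auto", "bilinear", "nearest")) {
  kind <- match.arg(kind)
  stopifnot(factor > 0)
  if (inherits(x, "gray_image")) {
    out <- resize(x$values, factor,
                  if (kind == "auto") "bilinear" else kind)
    out <- pmin(pmax(round_half_up(out), 0), 2^x$bit_depth - 1)
    return(gray_image(out, x$bit_depth, x$pixel_size / factor))
  }
  if (factor == 1) return(x)
  is_mask <- is.logical(x)
  if (kind == "auto") kind <- if (is_mask) "nearest" else "bilinear"
  nd <- round(dim(x) * factor)
  if (any(nd < 8)) stop("resized dimension below 8 px")
  filt <- if (kind == "nearest") "none" else "bilinear"
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(x * 1.0), w = nd[1], h = nd[2],
                    filter = filt))
  out <- matrix(out, nd[1], nd[2])
  if (is_mask) out > 0.5 else out
}

#' Resize a probability map to a target shape (bilinear)
#' @param values numeric matrix in [0, 1].
#' @param target_dim integer c(rows, cols).
#' @return numeric matrix of shape `target_dim`, clipped to [0, 1].
#' @keywords internal
resize_to <- function(values, target_dim) {
  if (identical(dim(values), as.integer(target_dim))) return(values)
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(values), w = target_dim[1],
                    h = target_dim[2], filter = "bilinear"))
  pmin(pmax(matrix(out, target_dim[1], target_dim[2]), 0), 1)
}

#' Split a manifest into train/validation/test by spheroid
#'
#' Every image of one spheroid goes to exactly one split, ruling out
#' leakage between groups through time-series correlation.  The split
#' is randomized over spheroid IDs; proportions are met as closely as
#' integer ID counts allow (largest-remainder rounding).
#'
#' @param entries data.frame with at least a `spheroid_id` column.
#' @param fractions numeric length 3 (train, val, test), summing to 1.
#' @param seed integer seed.
#' @return The manifest with a `split` column added.
#' @export
split_by_spheroid <- function(entries, fractions = c(0.8, 0.1, 0.1),
                              seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  ids <- unique(entries$spheroid_id)
  wanted <- c("train", "val", "test")[fractions > 0]
  if (length(ids) < length(wanted))
    stop("fewer spheroid IDs than non-empty splits")
  n <- length(ids)
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  # every requested split receives at least one ID
  for (j in which(fractions > 0 & cnt == 0)) {
    donor <- which.max(cnt)
    cnt[donor] <- cnt[donor] - 1
    cnt[j] <- cnt[j] + 1
  }
  shuffled <- with_seed(seed, sample(ids))
  assignment <- rep(c("train", "val", "test"), times = cnt)
  names(assignment) <- shuffled
  entries$split <- unname(assignment[as.character(entries$spheroid_id)])
  entries
}

#' Apply one orientation-preserving augmentation to an image/mask pair
#'
#' One of vertical flip, horizontal flip or rotation by 180 degrees,
#' chosen uniformly at random (or forced via `transform`); the same
#' transform is applied to image and mask so they stay aligned.  These
#' transforms keep the rectangular frame, so no border extrapolation is
#' needed.
#'
#' @param image matrix or `gray_image`.
#' @param mask logical matrix of the same shape.
#' @param transform `"random"`, `"vflip"`, `"hflip"` or `"rot180"`.
#' @return List with transformed `image`, `mask` and the `transform`
#'   used.
#' @export
augment_pair <- function(image, mask,
                         transform = c("random", "vflip", "hflip",
                                       "rot180")) {
  transform <- match.arg(transform)
  if (transform == "random")
    transform <- sample(c("vflip", "hflip", "rot180"), 1)
  img_values <- if (inherits(image, "gray_image")) image$values else image
  stopifnot_shape(img_values, mask)
  f <- switch(transform,
              vflip = function(m) m[nrow(m):1, , drop = FALSE],
              hflip = function(m) m[, ncol(m):1, drop = FALSE],
              rot180 = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE])
  out_img <- f(img_values)
  if (inherits(image, "gray_image"))
    out_img <- gray_image(out_img, image$bit_depth, image$pixel_size)
  list(image = out_img, mask = f(mask), transform = transform)
}

#' Double a training set by augmenting every item once
#'
#' Every original training sample is transformed exactly once with a
#' randomly picked flip/rotation, so the augmented set has twice the
#' original size; augmented copies keep the parent's spheroid ID.
#'
#' @param samples list of samples, each with `image`, `target` and
#'   `spheroid_id`.
#' @param seed integer seed for the transform draws.
#' @return List of length `2 * length(samples)`.
#' @export
build_training_set <- function(samples, seed = 1) {
  if (length(samples) == 0L) return(samples)
  with_seed(seed, {
    aug <- lapply(samples, function(s) {
      a <- augment_pair(s$image, s$target)
      s$image <- a$image
      s$target <- a$mask
      s$augmented <- a$transform
      s
    })
    c(samples, aug)
  })
}

#' Read/write gray-scale TIFF images
#'
#' 16-bit and 8-bit single-channel TIFFs; values round-trip in native
#' integer units.
#'
#' @param image a `gray_image`.
#' @param path file path.
#' @param pixel_size um/px to attach on read.
#' @return `write_gray_tiff` the path, `read_gray_tiff` a `gray_image`.
#' @export
write_gray_tiff <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  scale <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$values / scale, path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}

#' @rdname write_gray_tiff
#' @export
read_gray_tiff <- function(path, pixel_size = 2.04) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  bits <- if (max(v) > 255) 16 else attr(v, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(v) > 255) 16 else 8
  gray_image(v, bit_depth = if (bits > 8) 16 else 8,
             pixel_size = pixel_size)
}

#' Read/write a dataset manifest CSV
#'
#' Columns: `image`, `mask`, `spheroid_id` and optionally `split`.
#'
#' @param manifest data.frame.
#' @param path CSV file.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#' @param path YAML file of key-value pairs.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
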