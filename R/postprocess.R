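# Probability-map -> contour postprocessing chain, plus the classical
# Otsu thresholding baseline.

#' Threshold a probability map at 0.5
#'
#' Every pixel with probability greater than or equal to 0.5 is counted
#' as a spheroid pixel (the threshold is inclusive).
#'
#' @param prob a `prob_map` or numeric matrix in [0, 1].
#' @return logical mask.
#' @export
binarize <- function(prob) {
  v <- prob_values(prob)
  stopifnot(min(v) >= 0, max(v) <= 1)
  v >= 0.5
}

new_segmentation_result <- function(full_mask, components) {
  lc <- largest_component(components)
  contour <- if (any(lc$mask)) trace_contour(lc$mask) else NULL
  structure(list(full_mask = full_mask,
                 spheroid_mask = lc$mask,
                 contour = contour,
                 n_components = components$k,
                 ambiguous = components$k > 1L,
                 empty = components$k == 0L),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(paste0("segmentation_result: %d component(s), area %d px",
                     "%s%s\n"),
              x$n_components, sum(x$spheroid_mask),
              if (x$ambiguous) ", ambiguous" else "",
              if (x$empty) ", empty" else ""))
  invisible(x)
}

#' Extract the spheroid from a probability map
#'
#' The full chain: inclusive 0.5 thresholding, 8-connected component
#' labelling, selection of the largest component, and outer-border
#' following to the final polygonal chain.  An all-background map gives
#' an empty result (no contour).
#'
#' @param prob a `prob_map` or numeric matrix in [0, 1].
#' @param min_area optional minimum component area in px; smaller
#'   components are dropped before selection (default 0 = keep all).
#' @return Object of class `segmentation_result` with `full_mask`,
#'   `spheroid_mask` (largest component), `contour`, `n_components`,
#'   `ambiguous` and `empty`.
#' @export
extract_spheroid <- function(prob, min_area = 0) {
  full <- binarize(prob)
  comps <- label_components(full)
  if (min_area > 0 && comps$k > 0) {
    keep <- which(comps$areas >= min_area)
    full2 <- matrix(comps$labels %in% keep, nrow(full))
    comps <- label_components(full2)
  }
  new_segmentation_result(full, comps)
}

#' Classical Otsu thresholding baseline
#'
#' Otsu's threshold applied to the inverted 8-bit intensity (the
#' spheroid is dark on a bright background), followed by the same
#' component/contour chain as [extract_spheroid()].  Included as the
#' classical comparator that tends to fail on debris-obscured images.
#'
#' @param image 8-bit `gray_image` (16-bit input is converted first)
#'   or numeric matrix.
#' @return A `segmentation_result`; constant images give an empty
#'   result.
#' @export
otsu_baseline <- function(image) {
  img <- if (inherits(image, "gray_image")) to_8bit(image)
         else gray_image(image, 8)
  v <- img$values
  if (max(v) == min(v)) {
    comps <- label_components(matrix(FALSE, nrow(v), ncol(v)))
    return(new_segmentation_result(matrix(FALSE, nrow(v), ncol(v)),
                                   comps))
  }
  inv <- (255 - v) / 255
  thr <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1), levels = 256)
  full <- inv > thr
  new_segmentation_result(full, label_components(full))
}
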