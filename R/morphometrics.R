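# Spheroid shape characteristics derived from a segmentation mask.

#' Mean diameter of a mask
#'
#' The diameter of the circle with the mask's area,
#' `d = 2 sqrt(area / pi)`, in pixels; 0 for an empty mask.  This is
#' the size measure from which the spherical volume is estimated.
#'
#' @param mask logical matrix (or `segmentation_result`).
#' @return numeric diameter in px.
#' @export
mean_diameter <- function(mask) {
  2 * sqrt(sum(as_mask(mask)) / pi)
}

#' Spherical volume estimate from a diameter
#'
#' `pi d^3 / 6`, assuming the projected spheroid is the equator of a
#' sphere.
#'
#' @param diameter diameter (um for a volume in um^3).
#' @return numeric volume.
#' @export
sphere_volume <- function(diameter) {
  stopifnot(all(diameter >= 0))
  pi * diameter^3 / 6
}

#' Circularity of a mask
#'
#' `4 pi area / L^2` with `L` the outer polygonal chain length
#' (perimeter).  1 for an ideal circle; values may slightly exceed 1
#' for small digitized shapes because the chain length underestimates
#' the continuous perimeter, and are reported as computed.  Degenerate
#' components (< 3 chain points, L = 0) get circularity 1 with the
#' `degenerate` attribute set.
#'
#' @param mask logical matrix with a single component.
#' @param contour optional pre-computed `poly_chain` of the mask.
#' @return numeric circularity with attribute `degenerate`.
#' @export
circularity <- function(mask, contour = NULL) {
  mask <- as_mask(mask)
  if (is.null(contour)) contour <- trace_contour(mask)
  l <- chain_length(contour)
  if (l == 0) return(structure(1, degenerate = TRUE))
  structure(4 * pi * sum(mask) / l^2, degenerate = FALSE)
}

#' Morphometrics record for one mask
#'
#' Area, mean diameter (px and um), estimated spherical volume (um^3)
#' and circularity, as one data.frame row for results tables.
#'
#' @param mask logical matrix or `segmentation_result`.
#' @param pixel_size um/px of the native grid.
#' @return One-row data.frame: `area_px`, `diameter_px`, `diameter_um`,
#'   `volume_um3`, `circularity`, `degenerate`.
#' @export
morphometrics <- function(mask, pixel_size = 2.04) {
  contour <- NULL
  if (inherits(mask, "segmentation_result")) {
    contour <- mask$contour
    mask <- mask$spheroid_mask
  }
  area <- sum(as_mask(mask))
  d_px <- mean_diameter(mask)
  if (area == 0) {
    return(data.frame(area_px = 0, diameter_px = 0, diameter_um = 0,
                      volume_um3 = 0, circularity = 1, degenerate = TRUE))
  }
  circ <- circularity(mask, contour)
  data.frame(area_px = area, diameter_px = d_px,
             diameter_um = d_px * pixel_size,
             volume_um3 = sphere_volume(d_px * pixel_size),
             circularity = as.numeric(circ),
             degenerate = isTRUE(attr(circ, "degenerate")))
}
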