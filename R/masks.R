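# Pixel-set geometry: mask algebra, connected components, border
# following and polygonal chains.  A binary mask is a plain logical
# matrix indexed [row, col]; masks and images share the same raster
# grid with pixel-center coordinates.

#' Label 8-connected foreground components
#'
#' Components are labelled 1..k in raster-scan order of their first
#' pixel (rows top to bottom, columns left to right), which makes label
#' order deterministic.  Foreground connectivity is 8-neighbour,
#' background connectivity 4-neighbour, the standard pairing for border
#' following.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @return An object of class `component_set`: list with `labels`
#'   (integer matrix, 0 = background), `areas` (pixel count per label)
#'   and `k` (number of components).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
#' label_components(m)$k
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  if (length(mask) == 0L) stop("mask must be non-empty")
  lab <- label_components_cpp(mask)
  k <- attr(lab, "k")
  attr(lab, "k") <- NULL
  areas <- if (k > 0L) as.integer(tabulate(lab[lab > 0L], nbins = k))
           else integer(0)
  structure(list(labels = lab, areas = areas, k = k),
            class = "component_set")
}

#' Select the largest component of a labelled mask
#'
#' When several spheroids are detected in one image, downstream metrics
#' are computed on the largest component only; the presence of extra
#' components is reported through the `ambiguous` flag.  Ties in area
#' are broken by the lowest label (first component in raster-scan
#' order).
#'
#' @param components a `component_set` from [label_components()], or a
#'   logical mask (labelled on the fly).
#' @return List with `mask` (logical matrix of the largest component;
#'   all-`FALSE` when there is none) and `ambiguous` (`TRUE` when more
#'   than one component was present).
#' @export
largest_component <- function(components) {
  if (is.logical(components) || is.matrix(components))
    components <- label_components(components)
  stopifnot(inherits(components, "component_set"))
  if (components$k == 0L) {
    return(list(mask = matrix(FALSE, nrow(components$labels),
                              ncol(components$labels)),
                ambiguous = FALSE))
  }
  best <- which.max(components$areas)  # ties -> lowest label
  list(mask = components$labels == best, ambiguous = components$k > 1L)
}

#' Trace the outer border of a single component
#'
#' Moore-neighbour border following with Jacob's stopping criterion.
#' The result is a closed polygonal chain of border pixel centers in a
#' consistent counterclockwise (Cartesian convention) order; only the
#' outer border is traced, holes are ignored.
#'
#' @param component logical matrix containing exactly one 8-connected
#'   foreground component.
#' @return A `poly_chain`: list with `points` (n x 2 integer matrix of
#'   1-based (row, col) coordinates) and `closed` flag.
#' @export
trace_contour <- function(component) {
  component <- as_mask(component)
  cs <- label_components(component)
  if (cs$k > 1L)
    stop("mask has ", cs$k, " components; isolate one first ",
         "(see largest_component)")
  pts <- trace_contour_cpp(component)
  structure(list(points = pts, closed = TRUE), class = "poly_chain")
}

#' Length of a polygonal chain
#'
#' Sum of Euclidean distances between consecutive points, plus the
#' closing segment for closed chains.  Chains with fewer than two
#' points have length 0; the chain length is the perimeter estimate
#' used by [circularity()].
#'
#' @param chain a `poly_chain` or an n x 2 coordinate matrix.
#' @param closed closing-segment flag when a bare matrix is given.
#' @return numeric length in pixel units.
#' @export
chain_length <- function(chain, closed = TRUE) {
  if (inherits(chain, "poly_chain")) {
    closed <- isTRUE(chain$closed)
    chain <- chain$points
  }
  n <- nrow(chain)
  if (is.null(n) || n < 2L) return(0)
  d <- sqrt(diff(chain[, 1])^2 + diff(chain[, 2])^2)
  tot <- sum(d)
  if (closed)
    tot <- tot + sqrt(sum((chain[1, ] - chain[n, ])^2))
  tot
}

#' Intersection and union pixel counts of two masks
#'
#' @param p,t logical matrices of identical shape.
#' @return Named integer vector `c(intersection, union)`.
#' @export
mask_overlap <- function(p, t) {
  p <- as_mask(p); t <- as_mask(t)
  stopifnot_shape(p, t)
  i <- sum(p & t)
  c(intersection = i, union = sum(p) + sum(t) - i)
}

# Coerce numeric/logical raster to a logical mask matrix.
as_mask <- function(x) {
  if (inherits(x, "segmentation_result")) return(x$spheroid_mask)
  if (!is.matrix(x)) stop("a mask must be a matrix")
  if (!is.logical(x)) x <- x > 0
  x
}

#' Serialize a binary mask to an 8-bit PNG (0 background, 255 foreground)
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as_mask(mask)), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG file with 0/255 encoding.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v > 0.5
}

#' Export a contour as JSON or CSV
#'
#' JSON holds an array of `[row, col]` pairs; CSV one vertex per line
#' with a header.  Coordinates are written 0-based for interoperability
#' with array-indexing tools.
#'
#' @param chain a `poly_chain`.
#' @param path output file; format chosen from the extension
#'   (`.json` or `.csv`).
#' @export
write_contour <- function(chain, path) {
  stopifnot(inherits(chain, "poly_chain"))
  pts <- chain$points - 1L
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unname(apply(pts, 1, identity, simplify = FALSE)),
                         path, auto_unbox = FALSE)
  } else {
    write.csv(data.frame(row = pts[, 1], col = pts[, 2]), path,
              row.names = FALSE)
  }
  invisible(path)
}
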