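# Per-image and dataset-level segmentation accuracy metrics, and
# interobserver agreement statistics.

#' Jaccard distance between two masks
#'
#' `JCD = 1 - |P intersect T| / |P union T|`: the relative area error
#' of a segmentation, 0 when prediction and target overlap perfectly
#' and 1 when they are disjoint.  An empty prediction against a
#' non-empty target gives 1; an empty target is an error because the
#' target must be a valid manual segmentation.
#'
#' @param p predicted mask (logical matrix or `segmentation_result`).
#' @param t target mask, non-empty.
#' @return numeric in [0, 1].
#' @export
jcd <- function(p, t) {
  p <- as_mask(p); t <- as_mask(t)
  stopifnot_shape(p, t)
  if (!any(t)) stop("target mask must be non-empty")
  ov <- mask_overlap(p, t)
  1 - ov[["intersection"]] / ov[["union"]]
}

#' Relative deviation of a derived characteristic
#'
#' `|c_pred - c_target| / c_target`, used for the relative diameter
#' deviation (RDD) and relative circularity deviation (RCD).
#'
#' @param c_pred characteristic from the automatic segmentation.
#' @param c_target characteristic from the manual segmentation (> 0).
#' @return numeric >= 0.
#' @export
relative_deviation <- function(c_pred, c_target) {
  if (any(c_target <= 0)) stop("target characteristic must be positive")
  abs(c_pred - c_target) / c_target
}

#' Average radial error between two segmentations
#'
#' `delta_r = sqrt((|P union T| - |P intersect T|) / pi + d_T^2 / 4)
#' - d_T / 2` with `d_T` the target's mean diameter: the thickness of
#' the circular layer around a circle with the target's area whose
#' area equals the mismatched area `|P \\ T| + |T \\ P|`.  Excess and
#' missing areas do not compensate, so `delta_r` is larger than the
#' radial error implied by the diameter deviation alone.
#'
#' @param p predicted mask.
#' @param t target mask, non-empty.
#' @param pixel_size um/px; 1 reports the error in pixels.
#' @return numeric error in um (px when `pixel_size = 1`).
#' @export
delta_r <- function(p, t, pixel_size = 1) {
  p <- as_mask(p); t <- as_mask(t)
  stopifnot_shape(p, t)
  if (!any(t)) stop("target mask must be non-empty")
  ov <- mask_overlap(p, t)
  mism <- ov[["union"]] - ov[["intersection"]]
  dt <- mean_diameter(t)
  (sqrt(mism / pi + dt^2 / 4) - dt / 2) * pixel_size
}

#' Evaluate one predicted segmentation against its target
#'
#' Metrics are computed on the largest predicted component.  A
#' prediction with no overlap (`JCD = 1`) is invalid: it counts towards
#' the invalid spheroid fraction, RDD and RCD are set to 1, and the
#' radial error is computed against the empty prediction.  Extra
#' components beyond a valid largest one make the image ambiguous
#' (counted towards the ambiguous spheroid fraction) without affecting
#' the metrics.
#'
#' @param pred a `segmentation_result` (or a plain mask, treated as a
#'   single-component prediction).
#' @param target non-empty logical mask.
#' @param pixel_size um/px of the native grid.
#' @return One-row data.frame (`eval_record`): `jcd`, `iou`, `rdd`,
#'   `rcd`, `delta_r_px`, `delta_r_um`, `invalid`, `ambiguous`,
#'   `d_target_px`, `d_pred_px`, `circ_target`, `circ_pred`.
#' @export
evaluate_image <- function(pred, target, pixel_size = 2.04) {
  if (!inherits(pred, "segmentation_result")) {
    pm <- as_mask(pred)
    pred <- new_segmentation_result(pm, label_components(pm))
  }
  target <- as_mask(target)
  if (!any(target)) stop("target mask must be non-empty")
  stopifnot_shape(pred$spheroid_mask, target)

  j <- jcd(pred$spheroid_mask, target)
  invalid <- j == 1
  dtpx <- mean_diameter(target)
  circ_t <- as.numeric(circularity(largest_component(target)$mask))
  dr_px <- delta_r(pred$spheroid_mask, target, pixel_size = 1)
  if (invalid) {
    rdd <- 1; rcd <- 1
    dppx <- mean_diameter(pred$spheroid_mask)
    circ_p <- NA_real_
    ambiguous <- FALSE
    dr_px <- delta_r(matrix(FALSE, nrow(target), ncol(target)), target,
                     pixel_size = 1)
  } else {
    dppx <- mean_diameter(pred$spheroid_mask)
    circ_p <- as.numeric(circularity(pred$spheroid_mask, pred$contour))
    rdd <- relative_deviation(dppx, dtpx)
    rcd <- relative_deviation(circ_p, circ_t)
    ambiguous <- isTRUE(pred$ambiguous)
  }
  data.frame(jcd = j, iou = 1 - j, rdd = rdd, rcd = rcd,
             delta_r_px = dr_px, delta_r_um = dr_px * pixel_size,
             invalid = invalid, ambiguous = ambiguous,
             d_target_px = dtpx, d_pred_px = dppx,
             circ_target = circ_t, circ_pred = circ_p)
}

#' Summarize evaluation records over a dataset
#'
#' Mean, standard deviation and median of JCD, RDD, RCD and the radial
#' error; the invalid (ISF) and ambiguous (ASF) spheroid fractions with
#' the standard error of the mean of the corresponding binomial
#' distribution, `sqrt(p (1 - p) / n)`.
#'
#' @param records data.frame of rows from [evaluate_image()].
#' @return List of class `eval_summary`.
#' @export
summarize_evaluation <- function(records) {
  stopifnot(nrow(records) >= 1)
  n <- nrow(records)
  stat <- function(x) c(mean = mean(x), sd = if (n > 1) sd(x) else 0,
                        median = median(x))
  isf <- mean(records$invalid)
  asf <- mean(records$ambiguous)
  structure(list(
    n = n,
    jcd = stat(records$jcd),
    rdd = stat(records$rdd),
    rcd = stat(records$rcd),
    delta_r_px = stat(records$delta_r_px),
    delta_r_um = stat(records$delta_r_um),
    isf = c(fraction = isf, se = sqrt(isf * (1 - isf) / n)),
    asf = c(fraction = asf, se = sqrt(asf * (1 - asf) / n))),
    class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Evaluation over %d images\n", x$n))
  for (m in c("jcd", "rdd", "rcd")) {
    v <- x[[m]]
    cat(sprintf("  %-10s mean %.4f (%.1f%%)  sd %.4f  median %.4f\n",
                toupper(m), v["mean"], 100 * v["mean"], v["sd"],
                v["median"]))
  }
  v <- x$delta_r_um
  cat(sprintf("  delta_r    mean %.2f um  sd %.2f  median %.2f\n",
              v["mean"], v["sd"], v["median"]))
  cat(sprintf("  ISF        %.4f +/- %.4f\n", x$isf["fraction"],
              x$isf["se"]))
  cat(sprintf("  ASF        %.4f +/- %.4f\n", x$asf["fraction"],
              x$asf["se"]))
  invisible(x)
}

#' Pairwise Jaccard distances between raters
#'
#' For every image and every unordered pair of raters (human experts
#' and/or the model), the symmetric JCD between their masks.  Columns
#' are ordered lexicographically by pair name.
#'
#' @param masks_by_rater named list: rater -> list of masks, all over
#'   the same image sequence.
#' @return data.frame with one row per image and one `A~B` column per
#'   pair.
#' @export
interobserver_matrix <- function(masks_by_rater) {
  raters <- names(masks_by_rater)
  stopifnot(length(raters) >= 2)
  counts <- vapply(masks_by_rater, length, 0L)
  if (length(unique(counts)) != 1)
    stop("all raters must have segmented the same number of images")
  n <- counts[[1]]
  pairs <- utils::combn(sort(raters), 2)
  out <- matrix(0, n, ncol(pairs))
  colnames(out) <- apply(pairs, 2, paste, collapse = "~")
  for (j in seq_len(ncol(pairs))) {
    a <- masks_by_rater[[pairs[1, j]]]
    b <- masks_by_rater[[pairs[2, j]]]
    for (i in seq_len(n)) out[i, j] <- jcd(a[[i]], b[[i]])
  }
  as.data.frame(out, check.names = FALSE)
}

#' Friedman rank test over a block design
#'
#' Within-block average ranks (mean ranks on ties) give the statistic
#' `chi2_F = 12 / (n k (k + 1)) * sum(R_j^2) - 3 n (k + 1)`, divided by
#' the tie-correction factor `1 - sum(t^3 - t) / (n k (k^2 - 1))`; the
#' p-value comes from the chi-square distribution with `k - 1` degrees
#' of freedom.  Blocks that are entirely tied across all groups yield a
#' statistic of 0.
#'
#' @param table numeric matrix, n blocks (rows: images) x k groups
#'   (columns: rater pairs).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
friedman_test <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  stopifnot(n >= 2, k >= 2)
  ranks <- t(apply(table, 1, rank))
  rj <- colSums(ranks)
  num <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(table, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  stat <- if (abs(num) < 1e-12 || corr <= 0) 0 else num / corr
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Dunn-Bonferroni pairwise post hoc comparisons
#'
#' Dunn's z statistics from mean-rank differences with standard error
#' `sqrt(k (k + 1) / (6 n))`; two-sided p-values are multiplied by the
#' number of pairs (Bonferroni) and clipped at 1.
#'
#' @param table numeric matrix, n blocks x k groups.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`,
#'   sorted lexicographically by pair.
#' @export
dunn_bonferroni <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  stopifnot(n >= 2, k >= 2)
  if (is.null(colnames(table)))
    colnames(table) <- paste0("G", seq_len(k))
  ranks <- t(apply(table, 1, rank))
  mr <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(sort(colnames(table)), 2)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (j in seq_len(m)) {
    z[j] <- (mr[pairs[1, j]] - mr[pairs[2, j]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = pmin(p * m, 1))
}
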