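# Segmentation and HC-estimation accuracy metrics: Dice overlap on filled
# regions, Hausdorff and average symmetric surface distance on contour point
# sets (in mm), and MAE / percentage MAE on HC values.

#' Dice overlap index
#'
#' \eqn{\mathrm{Dice} = 2|S \cap G| / (|S| + |G|)} between two filled-region
#' masks of identical shape. Defined as 1 when both masks are empty. The Dice
#' index is independent of pixel spacing.
#'
#' @param seg,gt Binary masks (matrices) of identical dimensions.
#' @return A fraction in \[0, 1\].
#' @export
dice_index <- function(seg, gt) {
  if (!is.matrix(seg) || !is.matrix(gt))
    stop_invalid_input("masks must be matrices")
  if (!all(dim(seg) == dim(gt)))
    stop_invalid_input("mask shapes differ")
  if (!all(seg %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop_invalid_input("masks must be binary")
  s <- sum(seg); g <- sum(gt)
  if (s + g == 0) return(1)
  2 * sum(seg * gt) / (s + g)
}

# nearest-neighbor distances from each row of A to the point set B, after
# scaling coordinates to mm; chunked so the cross-distance matrix stays small.
nn_dists_mm <- function(A, B, spacing) {
  A <- cbind(A[, 1] * spacing$sx, A[, 2] * spacing$sy)
  B <- cbind(B[, 1] * spacing$sx, B[, 2] * spacing$sy)
  nb <- nrow(B)
  bs <- max(1L, floor(4e6 / nb))
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = bs)) {
    idx <- start:min(start + bs - 1L, nrow(A))
    # explicit coordinate differences (no a^2+b^2-2ab expansion, which loses
    # precision through cancellation)
    dx <- outer(A[idx, 1], B[, 1], "-")
    dy <- outer(A[idx, 2], B[, 2], "-")
    d2 <- dx * dx + dy * dy
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

check_pointset <- function(p, name) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    stop_invalid_input(sprintf("%s must be a nonempty n x 2 point matrix", name))
  p
}

#' Hausdorff distance between two contours (mm)
#'
#' The maximum over both directions of the point-to-nearest-point Euclidean
#' distance, with coordinates scaled by the pixel spacing before distances are
#' computed.
#'
#' @param c1,c2 Contour point sets: `n x 2` matrices of `(x, y)` pixel
#'   coordinates.
#' @param spacing A [pixel_spacing()] (mm/pixel); defaults to unit spacing.
#' @return Distance in mm.
#' @export
hausdorff_mm <- function(c1, c2, spacing = pixel_spacing(1)) {
  c1 <- check_pointset(c1, "c1"); c2 <- check_pointset(c2, "c2")
  max(max(nn_dists_mm(c1, c2, spacing)), max(nn_dists_mm(c2, c1, spacing)))
}

#' Average symmetric surface distance between two contours (mm)
#'
#' The mean of the two directed mean nearest-point distances:
#' \eqn{\mathrm{ASSD} = \tfrac12(\overline{d}(C_1 \to C_2) +
#' \overline{d}(C_2 \to C_1))}, in mm.
#'
#' @inheritParams hausdorff_mm
#' @return Distance in mm.
#' @export
assd_mm <- function(c1, c2, spacing = pixel_spacing(1)) {
  c1 <- check_pointset(c1, "c1"); c2 <- check_pointset(c2, "c2")
  (mean(nn_dists_mm(c1, c2, spacing)) + mean(nn_dists_mm(c2, c1, spacing))) / 2
}

#' HC estimation errors: MAE and percentage MAE
#'
#' MAE is the mean absolute difference between predicted and reference HC.
#' PMAE is the mean of the per-case percentage errors
#' \eqn{100\,|p_i - g_i| / g_i} (per-case ratios averaged, matching per-image
#' reporting).
#'
#' @param pred,gt Equal-length numeric vectors of HC values; `gt` must be
#'   positive.
#' @return A list with elements `mae` and `pmae` (percent).
#' @export
hc_errors <- function(pred, gt) {
  if (!is.numeric(pred) || !is.numeric(gt) || length(pred) != length(gt) ||
      length(gt) < 1L)
    stop_invalid_input("pred and gt must be equal-length numeric vectors")
  if (any(!is.finite(gt)) || any(gt <= 0))
    stop_invalid_input("reference HC values must be positive and finite")
  d <- abs(pred - gt)
  list(mae = mean(d), pmae = mean(100 * d / gt))
}

#' Full metrics report for one predicted/reference mask pair
#'
#' Computes Dice on the filled regions, Hausdorff and ASSD on the boundary
#' contours (via [boundary_points()]), and optionally the HC error if both HC
#' values are supplied.
#'
#' @param seg,gt Binary filled-region masks of identical shape.
#' @param spacing A [pixel_spacing()].
#' @param hc_pred,hc_gt Optional scalar HC values in mm.
#' @return A list of class `metrics_report` with keys `dice`, `hd_mm`,
#'   `assd_mm`, and (when HC values are given) `mae_mm`, `pmae_pct`.
#' @export
metrics_report <- function(seg, gt, spacing = pixel_spacing(1),
                           hc_pred = NULL, hc_gt = NULL) {
  rep <- list(dice = dice_index(seg, gt))
  cs <- boundary_points(seg); cg <- boundary_points(gt)
  rep$hd_mm <- hausdorff_mm(cs, cg, spacing)
  rep$assd_mm <- assd_mm(cs, cg, spacing)
  if (!is.null(hc_pred) && !is.null(hc_gt)) {
    e <- hc_errors(hc_pred, hc_gt)
    rep$mae_mm <- e$mae
    rep$pmae_pct <- e$pmae
  }
  structure(rep, class = "metrics_report")
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report` (or plain named list of scalars).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
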