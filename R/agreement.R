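# Method-agreement statistics: Bland-Altman analysis of predicted vs.
# reference HC, ordinary least-squares agreement regression, and the paired
# two-sided Student t-test used to compare two methods' error lists.
#
# Sign convention: differences are predicted - reference, so a negative bias
# means the method underestimates.

#' Bland-Altman analysis
#'
#' Computes the mean difference (bias), the 95% limits of agreement
#' `bias +/- 1.96 * sd` (sample standard deviation, n-1 denominator), and the
#' number of points falling strictly outside the limits. Differences are
#' `pred - gt`.
#'
#' @param pred,gt Equal-length numeric vectors (mm), `n >= 3`.
#' @return A list of class `agreement_report` with fields `bias`, `loa_low`,
#'   `loa_high`, `n_outliers`, `n_total`, plus the per-case `means` and
#'   `diffs` used for plotting.
#' @export
bland_altman <- function(pred, gt) {
  if (!is.numeric(pred) || !is.numeric(gt) || length(pred) != length(gt))
    stop_invalid_input("pred and gt must be equal-length numeric vectors")
  n <- length(pred)
  if (n < 3L)
    stop_insufficient_data("Bland-Altman analysis needs at least 3 pairs")
  d <- pred - gt
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  structure(list(
    bias = bias, loa_low = loa[1], loa_high = loa[2],
    n_outliers = sum(d < loa[1] | d > loa[2]), n_total = n,
    means = (pred + gt) / 2, diffs = d
  ), class = "agreement_report")
}

#' Agreement regression of predictions on reference values
#'
#' Ordinary least squares of `pred` on `gt`; `r2` is the squared Pearson
#' correlation. Perfect agreement gives slope 1, intercept 0, `r2` 1.
#'
#' @param pred,gt Equal-length numeric vectors, `n >= 3`; `gt` must not be
#'   constant.
#' @return A list with `slope`, `intercept`, `r2`.
#' @export
linfit <- function(pred, gt) {
  if (!is.numeric(pred) || !is.numeric(gt) || length(pred) != length(gt))
    stop_invalid_input("pred and gt must be equal-length numeric vectors")
  if (length(gt) < 3L)
    stop_insufficient_data("agreement regression needs at least 3 pairs")
  if (stats::sd(gt) == 0)
    stop_invalid_input("reference values are constant; regression is degenerate")
  fit <- stats::lm(pred ~ gt)
  r <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, gt)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r^2)
}

#' Paired two-sided Student t-test on two error lists
#'
#' Two-sided p-value of the paired t statistic on `errors_a - errors_b`.
#' Degenerate cases follow fixed conventions: if all differences are zero the
#' p-value is 1; if the differences have zero variance but nonzero mean the t
#' statistic is infinite and the p-value is 0.
#'
#' @param errors_a,errors_b Equal-length numeric vectors, `n >= 3`.
#' @return Two-sided p-value.
#' @export
paired_t <- function(errors_a, errors_b) {
  if (!is.numeric(errors_a) || !is.numeric(errors_b) ||
      length(errors_a) != length(errors_b))
    stop_invalid_input("error lists must be equal-length numeric vectors")
  if (length(errors_a) < 3L)
    stop_insufficient_data("paired t-test needs at least 3 pairs")
  d <- errors_a - errors_b
  m <- mean(d); s <- stats::sd(d)
  # zero-variance conventions (with float tolerance): all-zero differences
  # give p = 1; a constant nonzero difference is an infinite-t case, p = 0
  if (s <= 1e-12 * max(abs(d), 1e-300))
    return(if (abs(m) <= 1e-12 * max(abs(errors_a), abs(errors_b), 1e-300)) 1
           else 0)
  stats::t.test(errors_a, errors_b, paired = TRUE)$p.value
}

#' Full agreement report for one method (optionally vs. a competitor)
#'
#' Combines [bland_altman()], [linfit()], and, when a second method's absolute
#' errors are supplied, the [paired_t()] p-value comparing the two methods.
#'
#' @param pred,gt Equal-length numeric HC vectors (mm).
#' @param errors_other Optional absolute-error vector of a competing method on
#'   the same cases.
#' @return An `agreement_report` list with `bias`, `loa_low`, `loa_high`,
#'   `n_outliers`, `n_total`, `slope`, `intercept`, `r2` and `t_p_value`
#'   (`NA` when no competitor is given).
#' @export
agreement_report <- function(pred, gt, errors_other = NULL) {
  ba <- bland_altman(pred, gt)
  lf <- linfit(pred, gt)
  tp <- if (is.null(errors_other)) NA_real_ else
    paired_t(abs(pred - gt), errors_other)
  structure(c(ba[c("bias", "loa_low", "loa_high", "n_outliers", "n_total")],
              lf, list(t_p_value = tp),
              ba[c("means", "diffs")]),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f mm, 95%% LoA [%.3f, %.3f] mm, %d/%d outliers\n",
              x$bias, x$loa_low, x$loa_high, x$n_outliers, x$n_total))
  if (!is.null(x$slope))
    cat(sprintf("Agreement fit: pred = %.4f * gt + %.3f   (r2 = %.4f)\n",
                x$slope, x$intercept, x$r2))
  if (!is.null(x$t_p_value) && !is.na(x$t_p_value))
    cat(sprintf("Paired t-test vs. competitor: p = %.4g\n", x$t_p_value))
  invisible(x)
}

#' Write an agreement report to JSON
#'
#' Scalar fields only (the per-case vectors used for plotting are dropped).
#'
#' @param report An `agreement_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  keep <- setdiff(names(report), c("means", "diffs"))
  jsonlite::write_json(unclass(report)[keep], path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Bland-Altman and agreement scatter plots
#'
#' Writes a two-panel PNG: predicted vs. reference HC with the identity and
#' fitted lines, and the Bland-Altman plot (difference vs. mean) with bias and
#' 95% limits of agreement. Axes are labelled in mm.
#'
#' @param pred,gt Equal-length numeric HC vectors (mm).
#' @param path Output PNG path.
#' @param main Title prefix.
#' @return `path`, invisibly.
#' @export
plot_agreement <- function(pred, gt, path, main = "HC agreement") {
  ba <- bland_altman(pred, gt)
  lf <- linfit(pred, gt)
  grDevices::png(path, width = 1200, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(gt, pred, xlab = "reference HC (mm)",
                 ylab = "predicted HC (mm)",
                 main = paste(main, "- regression"), pch = 20)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(lf$intercept, lf$slope, col = "red")
  graphics::plot(ba$means, ba$diffs, xlab = "mean of measurements (mm)",
                 ylab = "difference pred - ref (mm)",
                 main = paste(main, "- Bland-Altman"), pch = 20)
  graphics::abline(h = ba$bias, col = "red")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "red")
  invisible(path)
}
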