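#' SSIM configuration
#'
#' Stabilizing constants for the global structural-similarity index. The
#' defaults follow the conventional choice \eqn{c_1 = (0.01 L)^2},
#' \eqn{c_2 = (0.03 L)^2} with dynamic range \eqn{L = 2}, matching images
#' normalized to \eqn{[-1, 1]}.
#'
#' @param dynamic_range Value range spanned by the images (default 2).
#' @param c1,c2 Stabilizing constants; computed from `dynamic_range` when
#'   omitted.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(dynamic_range = 2,
                        c1 = (0.01 * dynamic_range)^2,
                        c2 = (0.03 * dynamic_range)^2) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, dynamic_range = dynamic_range),
            class = "ssim_config")
}

#' Global structural similarity index
#'
#' Computes SSIM from whole-image (global) means, variances and covariance:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'                   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' Variances are population moments (divide by N). No sliding window is used;
#' the statistic is intended for ROI-sized patches where a single set of
#' global moments is meaningful.
#'
#' @param x,y Numeric matrices of identical dimension.
#' @param cfg An [ssim_config()].
#' @return A scalar in \eqn{[-1, 1]}; exactly 1 when `x == y`.
#' @export
ssim <- function(x, y, cfg = ssim_config()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical dimensions", call. = FALSE)
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  vx <- mean(dx * dx); vy <- mean(dy * dy)
  cxy <- mean(dx * dy)
  ((2 * mx * my + cfg$c1) * (2 * cxy + cfg$c2)) /
    ((mx * mx + my * my + cfg$c1) * (vx + vy + cfg$c2))
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, \eqn{2|A \cap B| / (|A| + |B|)}.
#' Two empty masks are defined to have Dice 1 (perfect agreement on "nothing").
#'
#' @param a,b Logical (or 0/1) matrices of identical dimension.
#' @return A scalar in \eqn{[0, 1]}.
#' @export
dice <- function(a, b) {
  a <- as.matrix(a) != 0; b <- as.matrix(b) != 0
  if (!identical(dim(a), dim(b))) stop("masks must have identical dimensions", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Circularity index from area and perimeter
#'
#' The roundness measure \eqn{4\pi A / p^2}: 1 for a perfect circle and
#' decreasing as the shape deforms. (Its reciprocal is sometimes printed as a
#' "motion-artefact severity"; this package uses the form that is 1 for a
#' circle, lies in \eqn{(0, 1]} and increases with quality.)
#'
#' @param area Shape area.
#' @param perimeter Shape perimeter, same length unit.
#' @return The circularity scalar.
#' @export
circularity_index <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive", call. = FALSE)
  }
  4 * pi * area / perimeter^2
}

#' Circularity of a binary vessel mask
#'
#' Measures how circular a segmented vessel cross-section is. Because area and
#' perimeter of a small rasterized shape carry discretization error (raw
#' boundary-pixel counting can even push the index above 1), the mask is first
#' enlarged by `upsample` with bilinear interpolation and smoothed with a
#' Gaussian of standard deviation equal to `upsample` pixels; the area is the
#' re-binarized (>= 0.5) foreground count and the perimeter is the length of
#' the sub-pixel 0.5 level-set polygon traced with marching squares. Both are
#' expressed in original-pixel units. The index is clipped to at most 1.
#'
#' @param mask Logical (or 0/1) matrix, non-empty.
#' @param upsample Integer enlargement factor (default 4).
#' @return An object of class `shape_measure`: list with `area`, `perimeter`,
#'   `circularity`.
#' @export
circularity <- function(mask, upsample = 4) {
  mask <- as.matrix(mask) != 0
  npx <- sum(mask)
  if (npx == 0) stop("mask is empty", call. = FALSE)
  if (npx < 5) stop("mask has fewer than 5 foreground pixels; shape measures are degenerate", call. = FALSE)
  f <- as.integer(upsample)
  if (f < 1) stop("upsample must be >= 1", call. = FALSE)
  up <- EBImage::resize(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                        w = nrow(mask) * f, h = ncol(mask) * f)
  up <- EBImage::imageData(EBImage::gblur(up, sigma = f))
  # zero border so the 0.5 level set always closes inside the domain
  pad <- matrix(0, nrow(up) + 2, ncol(up) + 2)
  pad[2:(nrow(up) + 1), 2:(ncol(up) + 1)] <- up
  area <- sum(up >= 0.5) / f^2
  if (area <= 0) stop("mask vanished after smoothing; too small for a shape measure", call. = FALSE)
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)), pad,
                                levels = 0.5)
  if (length(cl) == 0) stop("no 0.5 contour found", call. = FALSE)
  lens <- vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), numeric(1))
  perim <- max(lens) / f
  structure(list(area = area, perimeter = perim,
                 circularity = min(1, circularity_index(area, perim))),
            class = "shape_measure")
}

#' @export
print.shape_measure <- function(x, ...) {
  cat(sprintf("shape measure: area %.2f px^2, perimeter %.2f px, circularity %.4f\n",
              x$area, x$perimeter, x$circularity))
  invisible(x)
}

#' Segment the vessel lumen in a patch
#'
#' Thresholds at the midpoint between a robust background level (the median)
#' and a robust foreground level (the 99th percentile), fills holes, and keeps
#' the 8-connected component containing `hint_center` (or, if none contains
#' it, the component whose centroid is nearest to it).
#'
#' @param patch Numeric matrix (HU or normalized scale; the threshold is
#'   relative so either works).
#' @param hint_center Expected vessel position, 0-based `(row, col)`; defaults
#'   to the patch center.
#' @return A logical mask, or `NULL` (no-detection) when thresholding finds no
#'   foreground.
#' @export
segment_vessel <- function(patch, hint_center = NULL) {
  patch <- as.matrix(patch)
  stopifnot_finite(patch, "patch")
  if (is.null(hint_center)) hint_center <- (dim(patch) - 1) / 2
  thr <- (stats::median(patch) + stats::quantile(patch, 0.99, names = FALSE)) / 2
  bin <- patch > thr
  if (!any(bin)) return(NULL)
  bin <- EBImage::imageData(EBImage::fillHull(bin)) != 0
  lab <- label_components(bin)
  nlab <- max(lab)
  if (nlab == 1L) return(lab == 1L)
  hr <- hint_center[1] + 1; hc <- hint_center[2] + 1
  ir <- min(max(round(hr), 1), nrow(lab)); ic <- min(max(round(hc), 1), ncol(lab))
  if (lab[ir, ic] > 0) return(lab == lab[ir, ic])
  cent <- t(vapply(seq_len(nlab), function(k) mask_centroid(lab == k), numeric(2)))
  d2 <- (cent[, 1] - hint_center[1])^2 + (cent[, 2] - hint_center[2])^2
  lab == which.min(d2)
}

#' Paired or two-sample group comparison with a normality gate
#'
#' Compares two groups of continuous image-quality scores. Normality is
#' assessed with a Kolmogorov-Smirnov test against a normal distribution with
#' moment-estimated parameters (on the paired differences, or on each sample
#' for unpaired data) at alpha = 0.05. Normal data are compared with a (paired)
#' t test and summarized as mean +/- SD; otherwise a Wilcoxon signed-rank (or
#' rank-sum) test is used and groups are summarized as median (IQR). Tests are
#' two-sided with significance declared at p < 0.05.
#'
#' @param values_a,values_b Numeric vectors; equal length when `paired`.
#' @param paired Whether observations are paired (default TRUE).
#' @param alpha Significance level for both the normality gate and the verdict.
#' @return A list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `normal`, `significant`, `summary_a`, `summary_b`, `n`.
#' @export
compare_groups <- function(values_a, values_b, paired = TRUE, alpha = 0.05) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal-length samples", call. = FALSE)
  }
  if (length(a) < 5 || length(b) < 5) {
    stop("need at least 5 observations per group", call. = FALSE)
  }
  stopifnot_finite(a, "values_a"); stopifnot_finite(b, "values_b")

  ks_normal <- function(x) {
    if (stats::sd(x) < .Machine$double.eps^0.5) return(TRUE) # degenerate: no evidence against
    p <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
    p >= alpha
  }
  if (paired) {
    d <- a - b
    if (all(abs(d) < .Machine$double.eps^0.5)) {
      out <- list(test = "identical samples", statistic = 0, p_value = 1,
                  normal = TRUE, significant = FALSE,
                  summary_a = summarize_group(a, TRUE),
                  summary_b = summarize_group(b, TRUE), n = length(a))
      return(structure(out, class = "group_comparison"))
    }
    if (stats::sd(d) < .Machine$double.eps^0.5) {
      # constant nonzero shift: the t statistic diverges
      out <- list(test = "paired t test", statistic = sign(mean(d)) * Inf,
                  p_value = 0, normal = TRUE, significant = TRUE,
                  summary_a = summarize_group(a, TRUE),
                  summary_b = summarize_group(b, TRUE), n = length(a))
      return(structure(out, class = "group_comparison"))
    }
    normal <- ks_normal(d)
  } else {
    normal <- ks_normal(a) && ks_normal(b)
  }
  if (normal) {
    ht <- stats::t.test(a, b, paired = paired, alternative = "two.sided")
    test <- if (paired) "paired t test" else "t test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, alternative = "two.sided"))
    test <- if (paired) "Wilcoxon signed-rank test" else "Wilcoxon rank-sum test"
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 normal = normal,
                 significant = ht$p.value < alpha,
                 summary_a = summarize_group(a, normal),
                 summary_b = summarize_group(b, normal),
                 n = length(a)),
            class = "group_comparison")
}

summarize_group <- function(x, normal) {
  if (normal) {
    sprintf("%.3f ± %.3f", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3f (%.3f–%.3f)", q[2], q[1], q[3])
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n", x$test, x$statistic,
              x$p_value, if (x$significant) "significant" else "not significant"))
  cat(sprintf("  group A: %s\n  group B: %s\n", x$summary_a, x$summary_b))
  invisible(x)
}
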