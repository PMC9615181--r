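#' Evaluate correction quality over a set of paired samples
#'
#' For every pair: normalize both slices, run the generator on the artefact
#' slice (evaluation mode), segment the vessel in the raw, corrected and
#' reference images, and compute SSIM (vs reference), Dice (vs the reference
#' segmentation — the generative truth mask when the sample carries one) and
#' circularity. Samples where segmentation detects nothing are flagged and
#' excluded from group summaries with a logged count.
#'
#' @param samples A [generate_dataset()] result or list of `paired_sample`s.
#' @param generator A trained generator (or `gan_fit`), or `NULL` to evaluate
#'   the uncorrected pipeline (corrected = raw).
#' @param spec The [normalization_spec()] applied before the model and
#'   metrics.
#' @param upsample Circularity upsampling factor, see [circularity()].
#' @return A data frame of class `metrics_table` with one row per sample
#'   (`sample_id`, `detected`, `ssim_raw_vs_ref`, `ssim_corrected_vs_ref`,
#'   `dsc_raw_vs_ref`, `dsc_corrected_vs_ref`, `circ_raw`, `circ_corrected`,
#'   `circ_ref`) and a `summary` attribute with group means +/- SD.
#' @export
evaluate_pairs <- function(samples, generator = NULL,
                           spec = normalization_spec(), upsample = 4) {
  if (inherits(samples, "paired_dataset")) samples <- samples$samples
  if (inherits(generator, "gan_fit")) generator <- generator$generator
  if (length(samples) == 0) {
    out <- data.frame(sample_id = character(), detected = logical(),
                      ssim_raw_vs_ref = numeric(), ssim_corrected_vs_ref = numeric(),
                      dsc_raw_vs_ref = numeric(), dsc_corrected_vs_ref = numeric(),
                      circ_raw = numeric(), circ_corrected = numeric(),
                      circ_ref = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("metrics_table", "data.frame")
    return(out)
  }
  rows <- lapply(samples, function(s) {
    xn <- normalize_hu(s$artefact, spec)
    yn <- normalize_hu(s$reference, spec)
    cor <- if (is.null(generator)) xn else correct_image(generator, xn)
    hint <- if (!is.null(s$vessel_truth_mask) && any(s$vessel_truth_mask)) {
      mask_centroid(s$vessel_truth_mask)
    } else NULL
    seg_raw <- segment_vessel(xn, hint)
    seg_cor <- segment_vessel(cor, hint)
    ref_mask <- if (!is.null(s$vessel_truth_mask)) s$vessel_truth_mask else
      segment_vessel(yn, hint)
    detected <- !is.null(seg_raw) && !is.null(seg_cor) && !is.null(ref_mask) &&
      any(ref_mask)
    circ_of <- function(m) {
      if (is.null(m)) return(NA_real_)
      tryCatch(circularity(m, upsample)$circularity, error = function(e) NA_real_)
    }
    data.frame(
      sample_id = s$sample_id %||% NA_character_,
      detected = detected,
      ssim_raw_vs_ref = ssim(xn, yn),
      ssim_corrected_vs_ref = ssim(cor, yn),
      dsc_raw_vs_ref = if (detected) dice(seg_raw, ref_mask) else NA_real_,
      dsc_corrected_vs_ref = if (detected) dice(seg_cor, ref_mask) else NA_real_,
      circ_raw = circ_of(seg_raw),
      circ_corrected = circ_of(seg_cor),
      circ_ref = circ_of(if (is.logical(ref_mask) || is.numeric(ref_mask)) ref_mask else NULL),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_excluded <- sum(!out$detected)
  if (n_excluded > 0) {
    message(sprintf("evaluate_pairs: %d of %d samples had no vessel detection and are excluded from group summaries",
                    n_excluded, nrow(out)))
  }
  metric_cols <- setdiff(names(out), c("sample_id", "detected"))
  ok <- out$detected
  summ <- do.call(rbind, lapply(metric_cols, function(cn) {
    v <- out[[cn]][ok]
    v <- v[is.finite(v)]
    data.frame(metric = cn, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' @export
summary.metrics_table <- function(object, ...) {
  attr(object, "summary")
}

#' Paired comparisons of raw vs corrected metrics
#'
#' Runs the normality-gated paired comparison ([compare_groups()]) for each
#' metric family of a [evaluate_pairs()] table: corrected vs raw SSIM,
#' corrected vs raw Dice, and corrected vs raw circularity.
#'
#' @param metrics A `metrics_table`.
#' @return Named list of [compare_groups()] results
#'   (`ssim`, `dsc`, `circularity`).
#' @export
compare_metrics <- function(metrics) {
  m <- metrics[metrics$detected, , drop = FALSE]
  cmp <- function(a, b) {
    keep <- is.finite(a) & is.finite(b)
    compare_groups(a[keep], b[keep], paired = TRUE)
  }
  list(ssim = cmp(m$ssim_corrected_vs_ref, m$ssim_raw_vs_ref),
       dsc = cmp(m$dsc_corrected_vs_ref, m$dsc_raw_vs_ref),
       circularity = cmp(m$circ_corrected, m$circ_raw))
}
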