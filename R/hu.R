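#' CT slice in Hounsfield units
#'
#' A 2D grid of CT intensities in Hounsfield units (HU; water = 0, air ~
#' -1000) with pixel geometry. Coordinates throughout the package are
#' row-major, 0-based, pixel-center; boxes are half-open.
#'
#' @param pixels Numeric matrix of HU values, at least 8x8, all finite.
#' @param spacing Pixel spacing in mm (default 1).
#' @return An object of class `hu_slice` (a matrix with a `spacing` attribute).
#' @export
hu_slice <- function(pixels, spacing = 1.0) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    stop("a hu_slice needs at least 8x8 pixels", call. = FALSE)
  }
  stopifnot_finite(pixels, "pixels")
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  structure(pixels, spacing = spacing, class = c("hu_slice", "matrix", "array"))
}

#' @export
print.hu_slice <- function(x, ...) {
  cat(sprintf("hu_slice: %d x %d px, spacing %.3g mm, HU range [%.1f, %.1f]\n",
              nrow(x), ncol(x), attr(x, "spacing"), min(x), max(x)))
  invisible(x)
}

#' Rescale stored CT values to Hounsfield units
#'
#' Applies the standard affine CT rescale `HU = stored * slope + intercept`
#' element-wise (the slope/intercept pair that CT files carry in their
#' headers).
#'
#' @param stored_values Integer (or numeric) matrix of raw stored values.
#' @param slope Rescale slope; must be nonzero.
#' @param intercept Rescale intercept.
#' @param spacing Pixel spacing in mm passed through to the slice.
#' @return A [hu_slice()].
#' @export
to_hounsfield <- function(stored_values, slope = 1, intercept = -1024, spacing = 1.0) {
  if (slope == 0) stop("rescale slope must be nonzero", call. = FALSE)
  hu_slice(as.matrix(stored_values) * slope + intercept, spacing = spacing)
}

#' Normalization window specification
#'
#' The HU window mapped onto the model's \eqn{[-1, 1]} input range. The
#' defaults window soft tissue and contrast-enhanced lumen: \eqn{[-300, 500]}
#' HU.
#'
#' @param min_hu Lower window bound mapped to -1 (default -300).
#' @param max_hu Upper window bound mapped to +1 (default 500).
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(min_hu = -300, max_hu = 500) {
  if (!is.finite(min_hu) || !is.finite(max_hu) || max_hu <= min_hu) {
    stop("need finite max_hu > min_hu", call. = FALSE)
  }
  structure(list(min_hu = min_hu, max_hu = max_hu, out_low = -1, out_high = 1),
            class = "normalization_spec")
}

#' Normalize HU values to [-1, 1]
#'
#' Clamps to the window and applies the affine map
#' \eqn{M = (HU - MinHU)/(MaxHU - MinHU) \cdot 2 - 1}, so `min_hu` maps to -1
#' and `max_hu` to +1. Values outside the window are clamped first, keeping
#' the output range exactly \eqn{[-1, 1]} for any input.
#'
#' @param slice A [hu_slice()] or numeric matrix of HU values.
#' @param spec A [normalization_spec()].
#' @return A numeric matrix in \eqn{[-1, 1]}.
#' @seealso [denormalize_hu()] for the exact inverse on the window.
#' @export
normalize_hu <- function(slice, spec = normalization_spec()) {
  x <- unclass(as.matrix(slice))
  stopifnot_finite(x, "slice")
  x <- pmin(pmax(x, spec$min_hu), spec$max_hu)
  (x - spec$min_hu) / (spec$max_hu - spec$min_hu) * 2 - 1
}

#' Map normalized values back to Hounsfield units
#'
#' Exact inverse of [normalize_hu()] on the window: -1 recovers `min_hu`,
#' +1 recovers `max_hu`.
#'
#' @param m Numeric matrix in \eqn{[-1, 1]}.
#' @param spec A [normalization_spec()].
#' @return A numeric matrix of HU values in `[min_hu, max_hu]`.
#' @export
denormalize_hu <- function(m, spec = normalization_spec()) {
  m <- as.matrix(m)
  stopifnot_finite(m, "m")
  (m + 1) / 2 * (spec$max_hu - spec$min_hu) + spec$min_hu
}
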