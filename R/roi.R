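#' Locate the motion-artefact centroid from a raw/reference residual
#'
#' Motion artefacts live where a raw slice disagrees with its motion-corrected
#' reference. The absolute residual `|raw - reference|` is thresholded, cleaned
#' by binary morphology (opening then closing with a disc), and the centroid of
#' the largest 8-connected component is returned.
#'
#' When the fixed threshold detects nothing, an Otsu threshold on the residual
#' histogram is tried as a fallback before giving up.
#'
#' @param raw,reference Matrices (or [hu_slice()]s) of identical dimension, HU.
#' @param threshold_hu Residual threshold in HU (default 50).
#' @param morph_radius Disc radius in pixels for opening/closing (default 1).
#' @param otsu_fallback Try an Otsu threshold when the fixed one finds nothing.
#' @return A list of class `artifact_detection`: `detected` (logical),
#'   `centroid` (0-based `(row, col)` or `NULL`), `map` (logical artefact
#'   mask). Equal-area ties between components are broken toward the smaller
#'   row-then-column centroid.
#' @export
locate_artifact_centroid <- function(raw, reference, threshold_hu = 50,
                                     morph_radius = 1, otsu_fallback = TRUE) {
  raw <- unclass(as.matrix(raw)); reference <- unclass(as.matrix(reference))
  if (!identical(dim(raw), dim(reference))) {
    stop("raw and reference must have identical dimensions", call. = FALSE)
  }
  res <- abs(raw - reference)
  bin <- res > threshold_hu
  bin <- morph_clean(bin, morph_radius)
  if (!any(bin) && otsu_fallback && max(res) > 0) {
    scaled <- res / max(res)
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bin <- morph_clean(scaled > thr, morph_radius)
  }
  if (!any(bin)) {
    return(structure(list(detected = FALSE, centroid = NULL,
                          map = matrix(FALSE, nrow(raw), ncol(raw))),
                     class = "artifact_detection"))
  }
  lab <- label_components(bin)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    cents <- t(vapply(best, function(k) mask_centroid(lab == k), numeric(2)))
    best <- best[order(cents[, 1], cents[, 2])[1]]
  }
  comp <- lab == best
  structure(list(detected = TRUE, centroid = mask_centroid(comp), map = bin),
            class = "artifact_detection")
}

morph_clean <- function(bin, radius) {
  if (radius < 1 || !any(bin)) return(bin)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- EBImage::closing(EBImage::opening(bin, brush), brush)
  EBImage::imageData(out) != 0
}

#' Extract a model-input ROI around a centroid
#'
#' Crops a `crop` x `crop` window centered on the detected artefact centroid
#' (shifted minimally to lie fully inside the slice) and enlarges it to
#' `out` x `out` with bilinear interpolation — the coronary vessel occupies
#' only a small part of a CT slice, so the model operates on such patches.
#' The interpolation grid is corner-anchored: for integer enlargement factors
#' the crop's own pixels appear unchanged on a regular subgrid, so
#' [paste_roi()] recovers an untouched patch exactly.
#'
#' @param slice Numeric matrix, typically already normalized to \eqn{[-1, 1]}.
#' @param centroid 0-based `(row, col)` center for the crop window.
#' @param crop Crop window side in pixels (default 64).
#' @param out Output patch side after resizing (default 256).
#' @return An object of class `roi_patch`: `pixels` (`out` x `out`),
#'   `source_box` (half-open 0-based `(row0, row1, col0, col1)`), `centroid`,
#'   `crop`, `out`.
#' @export
extract_roi <- function(slice, centroid, crop = 64, out = 256) {
  slice <- unclass(as.matrix(slice))
  if (nrow(slice) < crop || ncol(slice) < crop) {
    stop(sprintf("slice (%d x %d) is smaller than the %d-pixel crop window",
                 nrow(slice), ncol(slice), crop), call. = FALSE)
  }
  r0 <- clamp_box_start(centroid[1], crop, nrow(slice))
  c0 <- clamp_box_start(centroid[2], crop, ncol(slice))
  win <- slice[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)]
  pixels <- if (out == crop) win else bilinear_resize(win, out)
  structure(list(pixels = pixels,
                 source_box = c(row0 = r0, row1 = r0 + crop,
                                col0 = c0, col1 = c0 + crop),
                 centroid = centroid, crop = crop, out = out),
            class = "roi_patch")
}

# 0-based start of a length-`crop` window centered at pixel-center coordinate
# `center`, shifted minimally to stay inside [0, n).
clamp_box_start <- function(center, crop, n) {
  s <- floor(center - crop / 2 + 0.5)
  as.integer(min(max(s, 0), n - crop))
}

# Corner-anchored bilinear resize: source pixel i sits at output index
# (i-1)*n_out/n_in + 1, so for integer enlargement factors the original
# samples appear unchanged on a regular subgrid and paste-back subsampling is
# an exact inverse. Rows beyond the last anchored sample replicate the edge.
interp_matrix <- function(n_in, n_out) {
  src <- pmin((seq_len(n_out) - 1) * n_in / n_out + 1, n_in)
  lo <- floor(src)
  hi <- pmin(lo + 1, n_in)
  w <- src - lo
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), lo)] <- M[cbind(seq_len(n_out), lo)] + (1 - w)
  M[cbind(seq_len(n_out), hi)] <- M[cbind(seq_len(n_out), hi)] + w
  M
}

bilinear_resize <- function(x, out_r, out_c = out_r) {
  interp_matrix(nrow(x), out_r) %*% x %*% t(interp_matrix(ncol(x), out_c))
}

#' Write a (corrected) ROI patch back into its source slice
#'
#' Inverse of [extract_roi()] for producing whole-slice output: the patch is
#' downsized to the crop size with bilinear interpolation, denormalized back
#' to HU, and written into its recorded source box. Pixels outside the box are
#' untouched.
#'
#' @param slice A [hu_slice()] or HU matrix.
#' @param patch An [extract_roi()] patch (values in \eqn{[-1, 1]}).
#' @param spec The [normalization_spec()] used when the patch was normalized.
#' @return The slice with the boxed region replaced.
#' @export
paste_roi <- function(slice, patch, spec = normalization_spec()) {
  x <- unclass(as.matrix(slice))
  b <- patch$source_box
  if (b["row0"] < 0 || b["col0"] < 0 || b["row1"] > nrow(x) || b["col1"] > ncol(x)) {
    stop("patch source_box lies outside the slice", call. = FALSE)
  }
  small <- if (patch$out == patch$crop) {
    patch$pixels
  } else if (patch$out %% patch$crop == 0) {
    # exact inverse of the corner-anchored enlargement
    idx <- (seq_len(patch$crop) - 1) * (patch$out %/% patch$crop) + 1
    patch$pixels[idx, idx]
  } else {
    bilinear_resize(patch$pixels, patch$crop)
  }
  x[(b["row0"] + 1):b["row1"], (b["col0"] + 1):b["col1"]] <- denormalize_hu(small, spec)
  if (inherits(slice, "hu_slice")) hu_slice(x, attr(slice, "spacing")) else x
}
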