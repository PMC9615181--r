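#' Vessel phantom parameters
#'
#' Describes one synthetic CT cross-section: a bright near-circular
#' contrast-filled vessel lumen on a soft-tissue background with a few
#' elliptical distractor structures. Fields left `NULL` are sampled per
#' phantom from the generation seed: vessel radius U(3, 8) px (at 64-pixel
#' scale, scaled proportionally), center uniform within the central 50% of the
#' frame, lumen U(300, 500) HU, background U(0, 80) HU.
#'
#' @param image_size Pixels per side (default 64, the native ROI crop size).
#' @param vessel_radius Radius in pixels, or `NULL` to sample.
#' @param vessel_center 0-based `(row, col)`, or `NULL` to sample.
#' @param lumen_hu Lumen intensity in HU, or `NULL` to sample.
#' @param background_hu Soft-tissue level in HU, or `NULL` to sample.
#' @param background_texture_sigma SD in HU of the smoothed background texture
#'   (default 15).
#' @param sensor_noise_sigma SD in HU of additive white sensor noise
#'   (default 10).
#' @param n_distractors Number of elliptical soft-tissue distractors
#'   (default 2).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 64, vessel_radius = NULL,
                           vessel_center = NULL, lumen_hu = NULL,
                           background_hu = NULL, background_texture_sigma = 15,
                           sensor_noise_sigma = 10, n_distractors = 2) {
  if (image_size < 16) stop("image_size must be at least 16", call. = FALSE)
  if (background_texture_sigma < 0 || sensor_noise_sigma < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 vessel_radius = vessel_radius, vessel_center = vessel_center,
                 lumen_hu = lumen_hu, background_hu = background_hu,
                 background_texture_sigma = background_texture_sigma,
                 sensor_noise_sigma = sensor_noise_sigma,
                 n_distractors = as.integer(n_distractors)),
            class = "phantom_params")
}

#' Cardiac-motion smear parameters
#'
#' A directional smear standing in for in-plane cardiac motion during
#' acquisition: the vessel is averaged over copies translated along
#' `direction` at offsets 0..`amplitude`, weighted by `exp(-decay * offset)`.
#' `amplitude = 0` is the identity.
#'
#' @param amplitude Total smear path in pixels, in \[0, 10\].
#' @param direction Radians; the displacement vector is
#'   `(cos(direction), sin(direction))` in `(row, col)`.
#' @param decay Weight-decay constant for the trailing tail (default 0.5).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(amplitude, direction = 0, decay = 0.5) {
  if (!is.finite(amplitude) || amplitude < 0 || amplitude > 10) {
    stop("amplitude must lie in [0, 10] pixels", call. = FALSE)
  }
  if (decay < 0) stop("decay must be non-negative", call. = FALSE)
  structure(list(amplitude = amplitude,
                 direction = direction %% (2 * pi), decay = decay),
            class = "motion_params")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Generate one vessel phantom
#'
#' Builds a reference (motion-free) slice: background level plus smoothed
#' zero-mean texture (white noise convolved with a Gaussian of 4-pixel SD at
#' 64-pixel scale, rescaled to the requested texture SD), elliptical
#' distractors, an exact disc of lumen intensity, and additive white sensor
#' noise. The returned mask marks the exact disc. Identical seeds give
#' bit-identical output.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed for all sampled quantities.
#' @return A list: `slice` (a [hu_slice()]), `mask` (logical lumen disc),
#'   `sampled` (the realized parameter values).
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  scale <- n / 64
  with_seed(seed, {
    r <- params$vessel_radius %||% (runif(1, 3, 8) * scale)
    cen <- params$vessel_center %||% runif(2, n / 4, 3 * n / 4 - 1)
    lumen <- params$lumen_hu %||% runif(1, 300, 500)
    bg <- params$background_hu %||% runif(1, 0, 80)
    if (cen[1] - r < 0 || cen[2] - r < 0 || cen[1] + r > n - 1 || cen[2] + r > n - 1) {
      stop(sprintf("vessel (center %.1f,%.1f radius %.1f) is not fully inside the %d-px frame",
                   cen[1], cen[2], r, n), call. = FALSE)
    }
    if (lumen <= bg + 100) {
      stop("lumen_hu must exceed background_hu by more than 100 HU", call. = FALSE)
    }
    rows <- matrix(0:(n - 1), n, n)
    cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
    img <- matrix(bg, n, n)
    if (params$background_texture_sigma > 0) {
      tex <- EBImage::imageData(
        EBImage::gblur(matrix(rnorm(n * n), n, n), sigma = 4 * scale))
      img <- img + tex / stats::sd(tex) * params$background_texture_sigma
    }
    if (params$n_distractors > 0) {
      for (k in seq_len(params$n_distractors)) {
        dc <- runif(2, 2, n - 3)
        ax <- runif(1, 4, 10) * scale; bx <- runif(1, 2, 6) * scale
        th <- runif(1, 0, pi)
        dhu <- runif(1, 40, 120)
        u <- (rows - dc[1]) * cos(th) + (cols - dc[2]) * sin(th)
        v <- -(rows - dc[1]) * sin(th) + (cols - dc[2]) * cos(th)
        img[(u / ax)^2 + (v / bx)^2 <= 1] <- img[(u / ax)^2 + (v / bx)^2 <= 1] + dhu
      }
    }
    mask <- (rows - cen[1])^2 + (cols - cen[2])^2 <= r^2
    img[mask] <- lumen
    if (params$sensor_noise_sigma > 0) {
      img <- img + matrix(rnorm(n * n, sd = params$sensor_noise_sigma), n, n)
    }
    list(slice = hu_slice(img),
         mask = mask,
         sampled = list(vessel_radius = r, vessel_center = cen,
                        lumen_hu = lumen, background_hu = bg, seed = seed))
  })
}

# Integer/fractional translation of a matrix with zero fill (bilinear for
# fractional shifts): out(i, j) = m(i - dr, j - dc).
shift_bilinear <- function(m, dr, dc) {
  fr <- floor(dr); fc <- floor(dc)
  ar <- dr - fr; ac <- dc - fc
  s <- function(r, c) int_shift(m, r, c)
  if (ar == 0 && ac == 0) return(s(fr, fc))
  (1 - ar) * (1 - ac) * s(fr, fc) + (1 - ar) * ac * s(fr, fc + 1) +
    ar * (1 - ac) * s(fr + 1, fc) + ar * ac * s(fr + 1, fc + 1)
}

int_shift <- function(m, r, c) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  src_r <- intersect(seq_len(n1) - r, seq_len(n1))
  src_c <- intersect(seq_len(n2) - c, seq_len(n2))
  if (length(src_r) == 0 || length(src_c) == 0) return(out)
  out[src_r + r, src_c + c] <- m[src_r, src_c]
  out
}

#' Smear the vessel of a reference slice with simulated cardiac motion
#'
#' Reproduces the comet-tail / crescent morphology of in-plane motion: the
#' vessel layer (masked foreground minus the local background level, estimated
#' as the median of a 3-pixel ring around the mask) is replaced by a weighted
#' average of copies translated along `direction` at unit offsets
#' `0..amplitude`, with weights proportional to `exp(-decay * offset)`
#' renormalized to sum to 1. The background is untouched. With `decay = 0` the
#' average preserves total vessel-layer intensity up to boundary clipping.
#'
#' @param reference A [hu_slice()] (or matrix), the motion-free slice.
#' @param mask Logical lumen mask within the slice bounds.
#' @param motion A [motion_params()].
#' @return The artefact slice, same class and dimensions as `reference`.
#' @export
apply_motion_artifact <- function(reference, mask, motion) {
  stopifnot(inherits(motion, "motion_params"))
  x <- unclass(as.matrix(reference))
  mask <- as.matrix(mask) != 0
  if (!identical(dim(mask), dim(x))) {
    stop("mask and reference must have identical dimensions", call. = FALSE)
  }
  if (motion$amplitude == 0) return(reference)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  dr1 <- cos(motion$direction); dc1 <- sin(motion$direction)
  idx <- which(mask, arr.ind = TRUE)
  end_r <- range(idx[, 1]) + motion$amplitude * dr1
  end_c <- range(idx[, 2]) + motion$amplitude * dc1
  if (min(end_r, range(idx[, 1])) < 1 || max(end_r) > nrow(x) ||
      min(end_c, range(idx[, 2])) < 1 || max(end_c) > ncol(x)) {
    stop(sprintf("smear path (amplitude %.1f px, direction %.2f rad) exits the frame",
                 motion$amplitude, motion$direction), call. = FALSE)
  }
  ring <- EBImage::imageData(EBImage::dilate(mask, EBImage::makeBrush(7, "disc"))) != 0
  ring <- ring & !mask
  bg_level <- stats::median(x[ring])
  layer <- (x - bg_level) * mask
  offsets <- seq(0, floor(motion$amplitude))
  if (motion$amplitude - floor(motion$amplitude) > 1e-9) {
    offsets <- c(offsets, motion$amplitude)
  }
  w <- exp(-motion$decay * offsets)
  w <- w / sum(w)
  smear <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(offsets)) {
    smear <- smear + w[k] * shift_bilinear(layer, offsets[k] * dr1, offsets[k] * dc1)
  }
  out <- x - layer + smear
  if (inherits(reference, "hu_slice")) hu_slice(out, attr(reference, "spacing")) else out
}

#' Generate a paired artefact/reference dataset
#'
#' Draws `n` independent phantoms, smears each with sampled motion, and
#' partitions them into train/validation/test splits in the given proportions
#' (default 40:30:27, so `n = 97` splits exactly 40/30/27). Phantoms whose
#' sampled smear path would exit the frame are re-drawn (deterministically
#' from the seed stream). Every sampled parameter is recorded in the manifest.
#'
#' @param n Number of pairs (>= 1).
#' @param params A [phantom_params()] template (NULL fields sampled per pair).
#' @param amplitude Either a fixed smear amplitude or a length-2 range to
#'   sample uniformly (default `c(2, 8)`).
#' @param direction Fixed direction in radians, or `NULL` to sample uniformly
#'   on \[0, 2\eqn{\pi}).
#' @param decay Smear weight decay (default 0.5).
#' @param seed Integer master seed; every per-sample stream derives from it.
#' @param split_ratio Train/validation/test proportions (default
#'   `c(40, 30, 27)`).
#' @return An object of class `paired_dataset`: `samples` (list of
#'   `paired_sample`: `artefact`, `reference`, `motion`, `vessel_truth_mask`,
#'   `segment_label`, `sample_id`) and `manifest` (data frame).
#' @export
generate_dataset <- function(n, params = phantom_params(), amplitude = c(2, 8),
                             direction = NULL, decay = 0.5, seed = 1,
                             split_ratio = c(40, 30, 27)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  labels <- c("pRCA-like", "mRCA-like", "dRCA-like")
  splits <- split_counts(n, split_ratio)
  split_col <- rep(c("train", "val", "test"), times = splits)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    amp <- with_seed(derive_seed(seed, 3L * i), {
      if (length(amplitude) == 2) runif(1, amplitude[1], amplitude[2]) else amplitude
    })
    dirn <- with_seed(derive_seed(seed, 3L * i + 1L), {
      direction %||% runif(1, 0, 2 * pi)
    })
    motion <- motion_params(amp, dirn, decay)
    ph <- NULL
    ph_seed <- NA_integer_
    for (attempt in 0:99) {
      ph_seed <- derive_seed(derive_seed(seed, 3L * i + 2L), attempt)
      cand <- generate_phantom(params, ph_seed)
      ok <- tryCatch({
        art <- apply_motion_artifact(cand$slice, cand$mask, motion)
        ph <- cand; ph$artefact <- art
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    if (is.null(ph)) {
      stop("could not place a smear path inside the frame after 100 attempts", call. = FALSE)
    }
    sid <- sprintf("s%04d", i)
    samples[[i]] <- structure(
      list(artefact = ph$artefact, reference = ph$slice, motion = motion,
           vessel_truth_mask = ph$mask,
           segment_label = labels[(i - 1) %% 3 + 1], sample_id = sid),
      class = "paired_sample")
    rows[[i]] <- data.frame(
      sample_id = sid, split = split_col[i], amplitude = amp,
      direction = dirn, decay = decay,
      radius = ph$sampled$vessel_radius,
      center_row = ph$sampled$vessel_center[1],
      center_col = ph$sampled$vessel_center[2],
      lumen_hu = ph$sampled$lumen_hu, background_hu = ph$sampled$background_hu,
      segment_label = labels[(i - 1) %% 3 + 1], seed = ph_seed,
      stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, manifest = do.call(rbind, rows), seed = seed),
            class = "paired_dataset")
}

split_counts <- function(n, ratio) {
  p <- cumsum(ratio) / sum(ratio)
  diff(c(0L, as.integer(round(p * n))))
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired_dataset: %d samples (%s)\n", length(x$samples),
              paste(sprintf("%s=%d", names(table(x$manifest$split)),
                            table(x$manifest$split)), collapse = ", ")))
  invisible(x)
}

#' Write / read a paired dataset bundle
#'
#' Serializes the samples as a single bundle (`samples.rds`) with the
#' manifest as `manifest.csv` and a JSON sidecar recording the master seed,
#' plus optional 8-bit windowed PNG previews per pair.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param preview_png Also write windowed 8-bit PNG previews (needs the
#'   `png` package).
#' @return `dir`, invisibly.
#' @export
write_paired_dataset <- function(ds, dir, preview_png = FALSE) {
  stopifnot(inherits(ds, "paired_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ds$samples, file.path(dir, "samples.rds"))
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(n = length(ds$samples), seed = ds$seed),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  if (preview_png && requireNamespace("png", quietly = TRUE)) {
    for (s in ds$samples) {
      img <- (normalize_hu(s$artefact) + 1) / 2
      png::writePNG(img, file.path(dir, paste0(s$sample_id, "_artefact.png")))
    }
  }
  invisible(dir)
}

#' @rdname write_paired_dataset
#' @export
read_paired_dataset <- function(dir) {
  samples <- readRDS(file.path(dir, "samples.rds"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"))
  structure(list(samples = samples, manifest = manifest, seed = meta$seed),
            class = "paired_dataset")
}
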