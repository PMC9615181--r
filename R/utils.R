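# Internal helpers shared across modules.

# 8-connected component labelling. EBImage::bwlabel() is 4-connected, so
# labels that touch diagonally are merged with a small union-find.
label_components <- function(mask) {
  mask <- mask != 0
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Centroid of TRUE pixels in 0-based pixel-center coordinates (row, col).
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

# Derive a per-item 32-bit seed from a base seed; keeps values in [1, 2^31-2].
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483646) + 1L
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
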