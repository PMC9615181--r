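test_that("noise-free phantom is exactly lumen inside the disc and background outside", {
  p <- noise_free_params(vessel_radius = 5, vessel_center = c(31.5, 31.5),
                         lumen_hu = 400, background_hu = 40)
  ph <- generate_phantom(p, seed = 1)
  expect_true(all(ph$slice[ph$mask] == 400))
  expect_true(all(ph$slice[!ph$mask] == 40))
  expect_identical(ph$mask, disc_mask(64, c(31.5, 31.5), 5))
})

test_that("equal seeds give bit-identical phantoms, different seeds differ", {
  a <- generate_phantom(phantom_params(), seed = 42)
  b <- generate_phantom(phantom_params(), seed = 42)
  c <- generate_phantom(phantom_params(), seed = 43)
  expect_identical(a, b)
  expect_false(identical(unclass(a$slice), unclass(c$slice)))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  generate_phantom(phantom_params(), seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("sampled lumen intensities are recovered in the mask mean", {
  # Monte-Carlo check of the generative contract: under default noise the
  # in-mask mean must track the sampled lumen HU (sensor noise is zero-mean)
  n <- 200
  devs <- vapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_params(), seed = 1000 + i)
    mean(ph$slice[ph$mask]) - ph$sampled$lumen_hu
  }, numeric(1))
  se <- sd(devs) / sqrt(n)
  expect_lt(abs(mean(devs)), 3 * se + 1e-9)
})

test_that("an out-of-frame vessel is rejected with a descriptive error", {
  p <- phantom_params(vessel_radius = 10, vessel_center = c(5, 32))
  expect_error(generate_phantom(p, seed = 1), "not fully inside")
  expect_error(generate_phantom(
    phantom_params(lumen_hu = 150, background_hu = 80), seed = 1),
    "exceed background")
})

test_that("zero-amplitude motion is the exact identity", {
  ph <- generate_phantom(phantom_params(), seed = 7)
  out <- apply_motion_artifact(ph$slice, ph$mask, motion_params(0, 1.3))
  expect_identical(out, ph$slice)
})

test_that("uniform-weight smear displaces the vessel centroid by amplitude/2", {
  p <- noise_free_params(vessel_radius = 6, vessel_center = c(24.5, 24.5),
                         lumen_hu = 400, background_hu = 20)
  ph <- generate_phantom(p, seed = 1)
  for (dir in c(0, pi / 4, pi / 2)) {
    m <- motion_params(6, dir, decay = 0)
    art <- apply_motion_artifact(ph$slice, ph$mask, m)
    layer_ref <- (unclass(ph$slice) - 20) * ph$mask
    layer_art <- unclass(art) - 20
    layer_art[layer_art < 0] <- 0
    cw <- function(w) {
      idx <- which(w > 1, arr.ind = TRUE)
      colSums(idx * w[w > 1]) / sum(w[w > 1])
    }
    shift <- cw(layer_art) - cw(layer_ref)
    want <- 3 * c(cos(dir), sin(dir))
    expect_lt(sqrt(sum((shift - want)^2)), 0.5)
  }
})

test_that("zero-decay smear conserves vessel-layer intensity within 1%", {
  p <- noise_free_params(vessel_radius = 5, vessel_center = c(28.5, 28.5),
                         lumen_hu = 450, background_hu = 30)
  ph <- generate_phantom(p, seed = 2)
  art <- apply_motion_artifact(ph$slice, ph$mask, motion_params(6, 0.7, decay = 0))
  total_ref <- sum((unclass(ph$slice) - 30)[ph$mask])
  total_art <- sum(unclass(art) - 30)
  expect_lt(abs(total_art - total_ref) / total_ref, 0.01)
})

test_that("a smear path that exits the frame is refused", {
  p <- noise_free_params(vessel_radius = 6, vessel_center = c(55, 55),
                         lumen_hu = 400, background_hu = 20)
  ph <- generate_phantom(p, seed = 1)
  expect_error(
    apply_motion_artifact(ph$slice, ph$mask, motion_params(10, pi / 4)),
    "exits the frame")
})

test_that("datasets are deterministic and split 97 samples as 40/30/27", {
  d1 <- generate_dataset(97, seed = 5)
  d2 <- generate_dataset(97, seed = 5)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$samples, d2$samples)
  expect_equal(as.vector(table(d1$manifest$split)[c("train", "val", "test")]),
               c(40, 30, 27))
})

test_that("amplitude forced to zero gives artefact == reference for every pair", {
  ds <- generate_dataset(5, amplitude = 0, seed = 3)
  for (s in ds$samples) expect_identical(s$artefact, s$reference)
})

test_that("manifest records the sampled motion and phantom parameters", {
  ds <- generate_dataset(6, seed = 9)
  m <- ds$manifest
  expect_setequal(names(m), c("sample_id", "split", "amplitude", "direction",
                              "decay", "radius", "center_row", "center_col",
                              "lumen_hu", "background_hu", "segment_label", "seed"))
  expect_true(all(m$amplitude >= 2 & m$amplitude <= 8))
  expect_true(all(m$lumen_hu > m$background_hu + 100))
  expect_equal(m$segment_label,
               rep(c("pRCA-like", "mRCA-like", "dRCA-like"), 2))
})

test_that("dataset bundles round-trip through disk", {
  ds <- generate_dataset(4, seed = 13)
  dir <- withr::local_tempdir()
  write_paired_dataset(ds, dir)
  back <- read_paired_dataset(dir)
  expect_identical(back$samples, ds$samples)
  expect_equal(back$manifest, ds$manifest)
  expect_equal(back$seed, 13)
})
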