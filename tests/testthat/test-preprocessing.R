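test_that("stored values rescale affinely to Hounsfield units", {
  expect_equal(unclass(to_hounsfield(matrix(0, 8, 8), 1, -1024))[1, 1], -1024)
  expect_equal(unclass(to_hounsfield(matrix(1024, 8, 8), 1, -1024))[1, 1], 0)
  g <- matrix(c(100, 200), 8, 8)
  expect_equal(unique(as.vector(to_hounsfield(g, 2, 10))), c(210, 410))
  expect_error(to_hounsfield(matrix(1, 8, 8), slope = 0), "nonzero")
})

test_that("normalization maps the default window endpoints and midpoint exactly", {
  s <- matrix(c(500, -300, 100, 1200), 8, 8)
  m <- normalize_hu(s)
  expect_identical(m[1, 1], 1)
  expect_identical(m[2, 1], -1)
  expect_identical(m[3, 1], 0)
  expect_identical(m[4, 1], 1) # clamped above the window
  expect_error(normalize_hu(matrix(c(NaN, 1:63), 8, 8)), "non-finite")
})

test_that("denormalize inverts normalize exactly on the window", {
  hu <- matrix(seq(-300, 500, length.out = 64), 8, 8)
  back <- denormalize_hu(normalize_hu(hu))
  expect_lt(max(abs(back - hu)), 1e-12)
  expect_identical(denormalize_hu(matrix(-1, 4, 4))[1, 1], -300)
  expect_identical(denormalize_hu(matrix(1, 4, 4))[1, 1], 500)
})

test_that("normalization is monotone and surjective onto [-1, 1]", {
  hu <- sort(runif(100, -600, 900))
  m <- as.vector(normalize_hu(matrix(hu, 10, 10)))
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(range(normalize_hu(matrix(seq(-300, 500, length.out = 100), 10, 10))),
               c(-1, 1))
})

test_that("zero residual yields the no-detection signal", {
  ref <- matrix(100, 32, 32)
  det <- locate_artifact_centroid(ref, ref)
  expect_false(det$detected)
  expect_null(det$centroid)
})

test_that("a planted residual block is localized to within a pixel", {
  ref <- matrix(50, 64, 64)
  raw <- ref
  raw[20:24, 30:34] <- raw[20:24, 30:34] + 200 # center (21, 31) 0-based
  det <- locate_artifact_centroid(raw, ref, threshold_hu = 50)
  expect_true(det$detected)
  expect_lt(max(abs(det$centroid - c(21, 31))), 1)
})

test_that("the largest of several artefact components is selected", {
  ref <- matrix(0, 64, 64)
  raw <- ref
  raw[10:14, 10:14] <- 300 # 25 px
  raw[40:42, 40:42] <- 300 # 9 px
  det <- locate_artifact_centroid(raw, ref, threshold_hu = 50)
  expect_lt(max(abs(det$centroid - c(11, 11))), 1e-9)
})

test_that("artefact localization is translation-equivariant", {
  base_raw <- matrix(0, 48, 48); base_ref <- matrix(0, 48, 48)
  base_raw[10:15, 12:16] <- 250
  d0 <- locate_artifact_centroid(base_raw, base_ref)
  for (sh in list(c(5, 7), c(11, 3))) {
    raw <- matrix(0, 48, 48)
    raw[10:15 + sh[1], 12:16 + sh[2]] <- 250
    d1 <- locate_artifact_centroid(raw, base_ref)
    expect_identical(d1$centroid, d0$centroid + sh)
  }
})

test_that("ROI crop boxes follow the half-open convention and clamp at borders", {
  sl <- matrix(rnorm(128 * 128), 128, 128)
  r <- extract_roi(sl, centroid = c(63.5, 63.5))
  expect_equal(unname(r$source_box), c(32, 96, 32, 96))
  expect_equal(dim(r$pixels), c(256, 256))
  r2 <- extract_roi(sl, centroid = c(0, 0))
  expect_equal(unname(r2$source_box), c(0, 64, 0, 64))
  expect_error(extract_roi(matrix(0, 32, 32), c(16, 16)), "smaller")
})

test_that("resizing a constant patch preserves the constant exactly", {
  sl <- matrix(0.37, 128, 128)
  r <- extract_roi(sl, centroid = c(63.5, 63.5))
  expect_true(all(r$pixels == 0.37))
})

test_that("extract/paste round-trip recovers the slice within 2% of the window", {
  ph <- generate_phantom(phantom_params(), seed = 21)
  hu <- ph$slice
  m <- normalize_hu(hu)
  patch <- extract_roi(m, centroid = c(31.5, 31.5), crop = 48, out = 192)
  back <- paste_roi(hu, patch)
  window <- 800 # default [-300, 500]
  expect_lt(max(abs(unclass(back) - unclass(hu))), 0.02 * window)
})

test_that("a constant -1 patch pastes as min_hu exactly and bad boxes fail", {
  hu <- hu_slice(matrix(100, 64, 64))
  patch <- extract_roi(normalize_hu(hu), centroid = c(31.5, 31.5), crop = 32, out = 128)
  patch$pixels[] <- -1
  out <- paste_roi(hu, patch)
  b <- patch$source_box
  expect_true(all(unclass(out)[(b["row0"] + 1):b["row1"], (b["col0"] + 1):b["col1"]] == -300))
  patch$source_box <- c(row0 = 40, row1 = 104, col0 = 0, col1 = 64)
  expect_error(paste_roi(hu, patch), "outside")
})
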