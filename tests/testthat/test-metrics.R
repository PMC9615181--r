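test_that("SSIM identities hold exactly", {
  set.seed(1)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  expect_identical(ssim(x, x), 1)
  # constant images: variance terms vanish, closed form remains
  a <- 0.3; b <- -0.2
  cfg <- ssim_config()
  want <- (2 * a * b + cfg$c1) / (a^2 + b^2 + cfg$c1)
  expect_equal(ssim(matrix(a, 8, 8), matrix(b, 8, 8)), want, tolerance = 1e-12)
  # anti-correlated zero-mean images score negative
  z <- x - mean(x)
  expect_lt(ssim(z, -z), 0)
  expect_error(ssim(x, matrix(0, 8, 8)), "dimensions")
})

test_that("SSIM is symmetric and bounded by 1", {
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(rnorm(256), 16, 16)
    y <- matrix(rnorm(256), 16, 16)
    expect_identical(ssim(x, y), ssim(y, x))
    expect_lte(ssim(x, y), 1)
  }
})

test_that("Dice handles identity, disjoint, partial overlap and empty masks", {
  m <- matrix(FALSE, 8, 8)
  a <- m; a[2:3, 2:3] <- TRUE        # 4 px
  b <- m; b[3:4, 2:3] <- TRUE        # 4 px, overlap 2
  d <- m; d[6:7, 6:7] <- TRUE
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, d), 0)
  expect_identical(dice(a, b), 0.5)
  expect_identical(dice(m, m), 1)    # both empty: agreement on nothing
  expect_identical(dice(a, !a), 0)
  expect_error(dice(a, matrix(FALSE, 4, 4)), "dimensions")
})

test_that("circularity index matches closed forms for circle and square", {
  r <- 3.7
  expect_equal(circularity_index(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  s <- 5
  expect_equal(circularity_index(s^2, 4 * s), pi / 4, tolerance = 1e-12)
})

test_that("rasterized discs measure within 0.02 of perfect circularity", {
  for (r in c(3, 4, 6, 8)) {
    m <- disc_mask(64, c(31.4, 32.6), r)
    sm <- circularity(m, upsample = 4)
    expect_gt(sm$circularity, 0.98)
    expect_lte(sm$circularity, 1)
  }
})

test_that("circularity strictly decreases along an ellipse axis-ratio sweep", {
  vals <- vapply(c(1, 2, 3, 4), function(ar) {
    m <- ellipse_mask(64, c(31.5, 31.5), 8 * sqrt(ar), 8 / sqrt(ar))
    circularity(m)$circularity
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("circularity is invariant to translation, rotation and scale", {
  m0 <- ellipse_mask(64, c(27.5, 30.5), 9, 5)
  c0 <- circularity(m0)$circularity
  m_shift <- ellipse_mask(64, c(33.5, 24.5), 9, 5)
  expect_lt(abs(circularity(m_shift)$circularity - c0), 1e-6)
  # 90-degree rotation of the grid is an exact symmetry
  m_rot <- t(m0)[, 64:1]
  expect_lt(abs(circularity(m_rot)$circularity - c0), 1e-6)
  # isotropic 2x rescaling changes only discretization
  m2 <- ellipse_mask(128, c(55, 61), 18, 10)
  expect_lt(abs(circularity(m2)$circularity - c0), 0.01)
})

test_that("degenerate masks are refused", {
  m <- matrix(FALSE, 16, 16)
  expect_error(circularity(m), "empty")
  m[4, 4] <- TRUE; m[5, 5] <- TRUE
  expect_error(circularity(m), "fewer than 5")
})

test_that("segmentation recovers the exact disc in the noise-free limit", {
  p <- noise_free_params(vessel_radius = 6, vessel_center = c(30.5, 33.5),
                         lumen_hu = 400, background_hu = 40)
  ph <- generate_phantom(p, seed = 1)
  seg <- segment_vessel(normalize_hu(ph$slice))
  expect_identical(seg, ph$mask)
  expect_null(segment_vessel(matrix(0.5, 32, 32)))
})

test_that("segmentation stays accurate under default noise (DSC >= 0.9)", {
  dscs <- vapply(1:100, function(i) {
    ph <- generate_phantom(phantom_params(), seed = 2000 + i)
    seg <- segment_vessel(normalize_hu(ph$slice),
                          hint_center = ns$mask_centroid(ph$mask))
    if (is.null(seg)) return(0)
    dice(seg, ph$mask)
  }, numeric(1))
  expect_gte(mean(dscs), 0.90)
})
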