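# Finite-difference checks of the layer backward passes. Sizes are tiny so
# the central-difference oracle stays cheap; tolerances reflect double
# precision with eps = 1e-5.

test_that("strided convolution gradients match finite differences", {
  set.seed(1)
  L <- ns$new_conv(3, 2, 3, stride = 2, pad = 1, init_sd = 0.3)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  y <- ns$conv_forward(L, x)
  dx <- ns$conv_backward(L, y) # dL/dy = y for loss sum(y^2)/2
  f <- function(xx) sum(ns$conv_forward(L, xx)^2) / 2
  expect_lt(max(abs(dx - numeric_grad(f, x))), 1e-6)
  ns$conv_forward(L, x); ns$conv_backward(L, y)
  fW <- function(W) {
    L2 <- ns$new_conv(3, 2, 3, stride = 2, pad = 1)
    L2$W <- W; L2$b <- L$b
    sum(ns$conv_forward(L2, x)^2) / 2
  }
  expect_lt(max(abs(L$dW - numeric_grad(fW, L$W))), 1e-6)
})

test_that("transposed convolution gradients match finite differences", {
  set.seed(2)
  for (spec in list(c(k = 4, s = 2, p = 1), c(k = 2, s = 2, p = 0))) {
    L <- ns$new_tconv(spec["k"], 2, 3, stride = spec["s"], pad = spec["p"],
                      init_sd = 0.3)
    x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
    y <- ns$tconv_forward(L, x)
    expect_equal(unname(dim(y)[1:2]), c(8, 8)) # doubles the spatial size
    dx <- ns$tconv_backward(L, y)
    f <- function(xx) sum(ns$tconv_forward(L, xx)^2) / 2
    expect_lt(max(abs(dx - numeric_grad(f, x))), 1e-6)
    ns$tconv_forward(L, x); ns$tconv_backward(L, y)
    fW <- function(W) {
      L2 <- ns$new_tconv(spec["k"], 2, 3, stride = spec["s"], pad = spec["p"])
      L2$W <- W; if (L2$bias) L2$b <- L$b
      sum(ns$tconv_forward(L2, x)^2) / 2
    }
    expect_lt(max(abs(L$dW - numeric_grad(fW, L$W))), 1e-6)
  }
})

test_that("batch-normalization training-mode gradient matches finite differences", {
  set.seed(3)
  L <- ns$new_bn(3)
  L$gamma <- runif(3, 0.5, 1.5); L$beta <- rnorm(3)
  x <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  y <- ns$bn_forward(L, x, train = TRUE)
  dx <- ns$bn_backward(L, y)
  f <- function(xx) sum(ns$bn_forward(L, xx, train = TRUE)^2) / 2
  expect_lt(max(abs(dx - numeric_grad(f, x))), 1e-6)
})

test_that("the full generator backward pass matches finite differences", {
  g <- build_generator(generator_spec(16, depth = 2, base_channels = 4,
                                      channel_cap = 8), seed = 3)
  g$layers$stem_conv$input_layer <- FALSE # keep the input gradient for the check
  set.seed(4)
  x <- array(rnorm(16 * 16, sd = 0.5), c(16, 16, 1, 1))
  y <- ns$gen_forward(g, x, train = TRUE)
  dx <- ns$gen_backward(g, y)
  f <- function(xx) sum(ns$gen_forward(g, xx, train = TRUE)^2) / 2
  idx <- sample(length(x), 6)
  num <- vapply(idx, function(i) {
    eps <- 1e-5
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(dx[idx] - num)), 1e-6)
})

test_that("generator preserves shape and range over assorted input sizes", {
  g <- build_generator(generator_spec_desk(), seed = 11)
  for (n in c(16, 32, 64)) {
    x <- matrix(runif(n * n, -1, 1), n, n)
    y <- ns$gen_forward(g, x, train = FALSE)
    expect_equal(dim(y), c(n, n, 1, 1))
    expect_true(all(y >= -1 & y <= 1))
  }
  expect_error(ns$gen_forward(g, matrix(0, 30, 30)), "divisible")
})

test_that("equal seeds give identical initial parameters", {
  a <- build_generator(generator_spec_desk(), seed = 5)
  b <- build_generator(generator_spec_desk(), seed = 5)
  expect_identical(ns$layers_state(a$layers), ns$layers_state(b$layers))
  c <- build_generator(generator_spec_desk(), seed = 6)
  expect_false(identical(ns$layers_state(a$layers), ns$layers_state(c$layers)))
})

test_that("desk generator parameter count equals the closed-form layer sum", {
  # hand summation over the declared layer table (depth 2, channels 16-32-64):
  # conv weights k*k*cin*cout (no bias before BN), BN gamma+beta = 2*cout,
  # output 1x1 conv with bias
  conv_bn <- function(k, cin, cout) k * k * cin * cout + 2 * cout
  expected <-
    conv_bn(3, 1, 16) +                     # stem
    conv_bn(4, 16, 32) +                    # down1
    conv_bn(3, 32, 32) + conv_bn(3, 32, 32) + # enc2 residual pair
    conv_bn(4, 32, 64) +                    # down2
    conv_bn(3, 64, 64) + conv_bn(3, 64, 64) + # bottleneck residual pair
    conv_bn(2, 64, 32) +                    # up2 (2x2 transposed)
    conv_bn(1, 64, 32) +                    # fuse2 on concat
    conv_bn(3, 32, 32) + conv_bn(3, 32, 32) + # dec2 residual pair
    conv_bn(2, 32, 16) +                    # up1
    conv_bn(1, 32, 16) +                    # fuse1 on concat
    conv_bn(3, 16, 16) + conv_bn(3, 16, 16) + # dec1 residual pair
    (1 * 1 * 16 * 1 + 1)                    # output conv + bias
  g <- build_generator(generator_spec_desk(), seed = 1)
  expect_equal(n_params(g), expected)
})
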