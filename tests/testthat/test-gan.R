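test_that("receptive field recurrence reproduces the canonical layer tables", {
  expect_identical(receptive_field(discriminator_spec()), 70)
  # single 4x4 stride-1 layer sees exactly its kernel
  expect_identical(receptive_field(discriminator_spec(channels = 1, strides = 1,
                                                      kernel = 4)), 4)
  # two stacked 3x3 stride-1 layers: 3 + 2 = 5
  expect_identical(receptive_field(discriminator_spec(channels = c(8, 1),
                                                      strides = c(1, 1),
                                                      kernel = 3)), 5)
  # desk variant keeps the same strides/kernels, hence the same field
  expect_identical(receptive_field(discriminator_spec_desk()), 70)
})

test_that("impulse-response footprint agrees with the recurrence", {
  # thin channels keep the brute-force pass cheap; the field depends only on
  # kernels and strides
  spec <- discriminator_spec(channels = c(4, 8, 8, 8, 1))
  expect_identical(receptive_field_impulse(spec, input_size = 96, seed = 3), 70L)
  small <- discriminator_spec(channels = c(4, 1), strides = c(1, 1), kernel = 3)
  expect_identical(receptive_field_impulse(small, input_size = 16, seed = 3), 5L)
})

test_that("discriminator scores lie in (0,1) and react to the candidate channel", {
  d <- build_discriminator(discriminator_spec_desk(), seed = 2)
  x <- matrix(0.1, 64, 64)
  out <- ns$disc_forward(d, x, matrix(0.2, 64, 64), train = FALSE)
  expect_true(all(out$scores > 0 & out$scores < 1))
  expect_true(is.finite(out$mean_score))
  set.seed(5)
  flipped <- ns$disc_forward(d, x, matrix(runif(64 * 64, -1, 1), 64, 64),
                             train = FALSE)
  expect_false(isTRUE(all.equal(out$mean_score, flipped$mean_score)))
  expect_error(ns$disc_forward(d, x, matrix(0, 32, 32)), "differ")
})

test_that("adversarial losses reproduce their closed forms", {
  half <- rep(0.5, 8)
  al <- adversarial_losses(half, half)
  expect_equal(al$loss_D, 2 * log(2), tolerance = 1e-12)
  expect_equal(al$adv_loss_G, log(2), tolerance = 1e-12)
  # perfect discriminator limit: clipped, loss_D near 0
  al2 <- adversarial_losses(rep(1, 4), rep(0, 4))
  expect_lt(al2$loss_D, 1e-5)
  # minimax form of the generator term
  al3 <- adversarial_losses(half, half, form = "minimax")
  expect_equal(al3$adv_loss_G, -log(2), tolerance = 1e-12)
})

test_that("L1 loss is the mean absolute difference", {
  a <- matrix(c(0.1, -0.1, 0.3, 0.1), 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(l1_loss(a, z), 0.15)
  expect_equal(l1_loss(z, z), 0)
  expect_equal(l1_loss(z + 0.25, z), 0.25)
  expect_error(l1_loss(z, matrix(0, 2, 3)), "shape")
})

test_that("the generator objective combines its terms linearly", {
  expect_equal(generator_objective(log(2), 0.15, loss_config(lambda_l1 = 10)),
               log(2) + 1.5)
  expect_equal(generator_objective(0.7, 0.3, loss_config(lambda_l1 = 0)), 0.7)
  expect_equal(generator_objective(0.7, 0, loss_config()), 0.7)
  expect_error(generator_objective(Inf, 0, loss_config()), "finite")
})

test_that("losses are permutation-invariant and non-negative", {
  set.seed(8)
  dr <- runif(20, 0.05, 0.95); df <- runif(20, 0.05, 0.95)
  p <- sample(20)
  expect_equal(adversarial_losses(dr, df), adversarial_losses(dr[p], df[p]))
  expect_gte(adversarial_losses(dr, df)$loss_D, 0)
  a <- matrix(rnorm(16), 4); b <- matrix(rnorm(16), 4)
  expect_gte(l1_loss(a, b), 0)
  expect_equal(l1_loss(a, b), l1_loss(b, a))
})
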