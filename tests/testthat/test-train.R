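# Small-step training runs: enough to exercise the loop, checkpointing and
# determinism contracts without long optimization.

make_pairs <- function(n, seed) generate_dataset(n, seed = seed)

test_that("training refuses a dataset smaller than one batch", {
  ds <- make_pairs(3, seed = 1)
  cfg <- train_config(profile = "desk", batch_size = 4, epochs = 1)
  expect_error(train_gan(ds, cfg), "at least batch_size")
})

test_that("the training loop is fully deterministic given the seed", {
  ds <- make_pairs(8, seed = 2)
  cfg <- train_config(profile = "desk", steps = 6, epochs = 100, seed = 9)
  f1 <- train_gan(ds, cfg)
  f2 <- train_gan(ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(ns$layers_state(f1$generator$layers),
                   ns$layers_state(f2$generator$layers))
  f3 <- train_gan(ds, train_config(profile = "desk", steps = 6, epochs = 100,
                                   seed = 10))
  expect_false(identical(f1$history, f3$history))
})

test_that("losses stay finite and are recorded per step", {
  ds <- make_pairs(8, seed = 3)
  fit <- train_gan(ds, train_config(profile = "desk", steps = 8, epochs = 100,
                                    seed = 4))
  h <- fit$history
  expect_equal(nrow(h), 8)
  expect_true(all(is.finite(as.matrix(h))))
  expect_equal(h$obj_g, h$adv_g + 10 * h$l1, tolerance = 1e-12)
})

test_that("resuming a checkpoint reproduces the continued run bit-for-bit", {
  ds <- make_pairs(8, seed = 5)
  dir <- withr::local_tempdir()
  # uninterrupted run: 2 epochs (2 steps each)
  cfg_full <- train_config(profile = "desk", epochs = 2, seed = 11)
  full <- train_gan(ds, cfg_full)
  # interrupted: 1 epoch with a checkpoint, then resume to epoch 2
  cfg_half <- train_config(profile = "desk", epochs = 1, seed = 11,
                           checkpoint_every = 1, checkpoint_dir = dir)
  train_gan(ds, cfg_half)
  ck <- file.path(dir, "checkpoint_epoch0001.rds")
  expect_true(file.exists(ck))
  resumed <- train_gan(ds, cfg_full, resume = ck)
  expect_identical(resumed$history, full$history)
  expect_identical(ns$layers_state(resumed$generator$layers),
                   ns$layers_state(full$generator$layers))
})

test_that("correction is deterministic, shape-preserving and bounded", {
  g <- build_generator(generator_spec_desk(), seed = 21)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  y1 <- correct_image(g, x)
  y2 <- correct_image(g, x)
  expect_identical(y1, y2)
  expect_equal(dim(y1), dim(x))
  expect_true(all(y1 >= -1 & y1 <= 1))
  expect_error(correct_image(g, matrix(0, 30, 30)), "divisible")
  # roi_patch in, roi_patch out
  patch <- extract_roi(x, centroid = c(31.5, 31.5), crop = 32, out = 64)
  out <- correct_image(g, patch)
  expect_s3_class(out, "roi_patch")
  expect_identical(out$source_box, patch$source_box)
})

test_that("a short optimization reduces the reconstruction loss", {
  ds <- make_pairs(16, seed = 6)
  fit <- train_gan(ds, train_config(profile = "desk", steps = 60, epochs = 1000,
                                    seed = 7))
  h <- fit$history
  expect_lt(median(h$l1[51:60]), median(h$l1[1:10]))
})
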