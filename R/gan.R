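#' Generator architecture specification
#'
#' A Res-UNet: an encoder-decoder with long skip connections (concatenation
#' from each encoder stage to its mirror decoder stage) whose convolution
#' blocks carry identity residual shortcuts. Downsampling is by stride-2
#' convolution, upsampling by stride-2 transposed convolution; batch
#' normalization follows every convolution except the output layer. The
#' network output is a global residual — what to add to or subtract from the
#' input in the pre-squash domain — and the sum is squashed onto
#' \eqn{[-1, 1]} by `tanh`, so untouched regions pass through unchanged. The default matches a
#' 256x256 single-channel input; the `desk` profile (depth 2, 16 base
#' channels, 64x64 input) is a scaled-down variant for CPU-sized experiments.
#'
#' @param input_size Expected square input side (must be divisible by
#'   `2^depth`); the network is fully convolutional, so other divisible sizes
#'   also work at inference.
#' @param depth Number of downsampling stages (default 4).
#' @param base_channels Channels after the stem (default 64), doubling per
#'   stage up to `channel_cap`.
#' @param channel_cap Maximum channel width (default 512).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 256, depth = 4, base_channels = 64,
                           channel_cap = 512) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (input_size %% 2^depth != 0) {
    stop(sprintf("input_size %d is not divisible by 2^%d", input_size, depth),
         call. = FALSE)
  }
  structure(list(input_size = input_size, depth = depth,
                 base_channels = base_channels, channel_cap = channel_cap),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @export
generator_spec_desk <- function() generator_spec(64, depth = 2, base_channels = 16)

#' Patch discriminator architecture specification
#'
#' A convolutional discriminator that scores overlapping patches of the
#' (source, candidate) channel pair as real or fake and averages the per-patch
#' sigmoid scores into one scalar. The default layer table — 4x4 kernels with
#' strides (2, 2, 2, 1, 1) and channels (64, 128, 256, 512, 1) — gives each
#' pre-average output unit a theoretical receptive field of 70x70 input
#' pixels. Batch normalization on every layer except the first and last.
#'
#' @param channels Output channels per layer.
#' @param strides Stride per layer.
#' @param kernel Square kernel side shared by all layers (default 4).
#' @param in_channels Input channels (default 2: source plus candidate).
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(channels = c(64, 128, 256, 512, 1),
                               strides = c(2, 2, 2, 1, 1), kernel = 4,
                               in_channels = 2) {
  if (length(channels) != length(strides) || length(channels) == 0) {
    stop("channels and strides must be non-empty and of equal length", call. = FALSE)
  }
  structure(list(channels = channels, strides = strides, kernel = kernel,
                 in_channels = in_channels),
            class = "discriminator_spec")
}

#' @rdname discriminator_spec
#' @export
discriminator_spec_desk <- function() {
  discriminator_spec(channels = c(8, 16, 32, 64, 1))
}

#' Theoretical receptive field of the patch discriminator
#'
#' Applies the standard recurrence \eqn{RF_k = RF_{k+1} \cdot s_k + (k_k -
#' s_k)} from the deepest layer back to the input, giving the side of the
#' input patch seen by one pre-average output unit.
#'
#' @param spec A [discriminator_spec()].
#' @return Receptive-field side in pixels (70 for the default spec).
#' @seealso [receptive_field_impulse()] for the brute-force check.
#' @export
receptive_field <- function(spec) {
  rf <- 1
  for (i in rev(seq_along(spec$strides))) {
    rf <- rf * spec$strides[i] + (spec$kernel - spec$strides[i])
  }
  rf
}

#' Receptive field measured by impulse response
#'
#' Brute-force cross-check of [receptive_field()]: builds the discriminator
#' with random parameters, backpropagates a unit impulse from one central
#' pre-average output unit, and measures the width of the nonzero gradient
#' footprint on the input. With leaky-rectified activations the footprint
#' equals the exact index support.
#'
#' @param spec A [discriminator_spec()].
#' @param input_size Input side; must comfortably exceed the expected field.
#' @param seed Seed for the random parameters.
#' @return Footprint side in pixels.
#' @export
receptive_field_impulse <- function(spec = discriminator_spec(),
                                    input_size = 96, seed = 7) {
  d <- build_discriminator(spec, seed = seed)
  n <- input_size
  x <- with_seed(seed, array(rnorm(n * n), c(n, n, 1, 1)))
  y <- with_seed(seed + 1, array(rnorm(n * n), c(n, n, 1, 1)))
  out <- disc_forward(d, x, y, train = FALSE)
  dz <- array(0, dim(out$pre))
  ctr <- pmax(1, floor(dim(out$pre)[1:2] / 2))
  dz[ctr[1], ctr[2], 1, 1] <- 1
  dx <- disc_backward(d, dz)
  hit <- apply(abs(dx) > 0, c(1, 2), any)
  rows <- range(which(apply(hit, 1, any)))
  cols <- range(which(apply(hit, 2, any)))
  max(diff(rows), diff(cols)) + 1L
}

#' Build the Res-UNet generator
#'
#' Allocates all layer parameters with a deterministic zero-mean normal
#' initialization (SD 0.02) from `seed`. The returned object maps any
#' \eqn{[-1,1]} grid whose sides are divisible by `2^depth` to a
#' \eqn{[-1,1]} grid of the same shape.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer initialization seed; equal seeds give identical
#'   parameters.
#' @return An object of class `gan_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth
  ch <- pmin(spec$base_channels * 2^(0:d), spec$channel_cap)
  g <- new.env(parent = emptyenv())
  g$spec <- spec
  g$ch <- ch
  # encoder residual pairs operate at the coarser scales (stages 2..d, plus
  # the bottleneck); the full-resolution encoder stage is a lightweight stem,
  # with detail carried by the long skip. Every decoder stage, including the
  # full-resolution one, ends in a residual pair so the output can form
  # sharp sub-pixel edges
  with_seed(seed, {
    ly <- list()
    ly$stem_conv <- new_conv(3, 1, ch[1], bias = FALSE)
    ly$stem_conv$input_layer <- TRUE
    ly$stem_bn <- new_bn(ch[1])
    for (i in seq_len(d)) {
      if (i > 1) {
        ly[[paste0("enc", i, "_rc1")]] <- new_conv(3, ch[i], ch[i], bias = FALSE)
        ly[[paste0("enc", i, "_rb1")]] <- new_bn(ch[i])
        ly[[paste0("enc", i, "_rc2")]] <- new_conv(3, ch[i], ch[i], bias = FALSE)
        ly[[paste0("enc", i, "_rb2")]] <- new_bn(ch[i])
      }
      ly[[paste0("down", i, "_conv")]] <- new_conv(4, ch[i], ch[i + 1], stride = 2, pad = 1, bias = FALSE)
      ly[[paste0("down", i, "_bn")]] <- new_bn(ch[i + 1])
    }
    ly$bott_rc1 <- new_conv(3, ch[d + 1], ch[d + 1], bias = FALSE)
    ly$bott_rb1 <- new_bn(ch[d + 1])
    ly$bott_rc2 <- new_conv(3, ch[d + 1], ch[d + 1], bias = FALSE)
    ly$bott_rb2 <- new_bn(ch[d + 1])
    for (i in rev(seq_len(d))) {
      ly[[paste0("up", i, "_tconv")]] <- new_tconv(2, ch[i + 1], ch[i], stride = 2, pad = 0, bias = FALSE)
      ly[[paste0("up", i, "_bn")]] <- new_bn(ch[i])
      ly[[paste0("fuse", i, "_conv")]] <- new_conv(1, 2 * ch[i], ch[i], pad = 0, bias = FALSE)
      ly[[paste0("fuse", i, "_bn")]] <- new_bn(ch[i])
      ly[[paste0("dec", i, "_rc1")]] <- new_conv(3, ch[i], ch[i], bias = FALSE)
      ly[[paste0("dec", i, "_rb1")]] <- new_bn(ch[i])
      ly[[paste0("dec", i, "_rc2")]] <- new_conv(3, ch[i], ch[i], bias = FALSE)
      ly[[paste0("dec", i, "_rb2")]] <- new_bn(ch[i])
    }
    ly$out_conv <- new_conv(1, ch[1], 1, pad = 0)
    g$layers <- ly
  })
  class(g) <- "gan_generator"
  g
}

#' @export
print.gan_generator <- function(x, ...) {
  cat(sprintf("gan_generator: Res-UNet depth %d, channels %s, %d parameters\n",
              x$spec$depth, paste(x$ch, collapse = "-"), n_params(x)))
  invisible(x)
}

#' Number of learnable parameters of a model
#' @param model A [build_generator()] or [build_discriminator()] object.
#' @return Integer parameter count.
#' @export
n_params <- function(model) n_params_layers(model$layers)

resblock_forward <- function(ly, pre, x, train) {
  p1 <- conv_forward(ly[[paste0(pre, "_rc1")]], x)
  q1 <- bn_forward(ly[[paste0(pre, "_rb1")]], p1, train)
  a1 <- lrelu_forward(q1)
  p2 <- conv_forward(ly[[paste0(pre, "_rc2")]], a1)
  q2 <- bn_forward(ly[[paste0(pre, "_rb2")]], p2, train)
  s <- q2 + x
  list(y = lrelu_forward(s), q1 = q1, s = s)
}

resblock_backward <- function(ly, pre, cache, dy) {
  ds <- lrelu_backward(dy, cache$s)
  da1 <- conv_backward(ly[[paste0(pre, "_rc2")]],
                       bn_backward(ly[[paste0(pre, "_rb2")]], ds))
  dq1 <- lrelu_backward(da1, cache$q1)
  dx <- conv_backward(ly[[paste0(pre, "_rc1")]],
                      bn_backward(ly[[paste0(pre, "_rb1")]], dq1))
  dx + ds
}

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1, 1))
  else if (length(dim(x)) == 3) array(x, c(dim(x), 1))
  else x
}

gen_forward <- function(g, x, train = TRUE) {
  x <- as_batch(x)
  d <- g$spec$depth
  if (any(dim(x)[1:2] %% 2^d != 0)) {
    stop(sprintf("generator input %dx%d is not divisible by 2^%d",
                 dim(x)[1], dim(x)[2], d), call. = FALSE)
  }
  ly <- g$layers
  fc <- list()
  q0 <- bn_forward(ly$stem_bn, conv_forward(ly$stem_conv, x), train)
  cur <- lrelu_forward(q0)
  fc$q0 <- q0
  skips <- list()
  for (i in seq_len(d)) {
    if (i > 1) {
      rb <- resblock_forward(ly, paste0("enc", i), cur, train)
      fc[[paste0("enc", i)]] <- rb[c("q1", "s")]
      cur <- rb$y
    }
    skips[[i]] <- cur
    qd <- bn_forward(ly[[paste0("down", i, "_bn")]],
                     conv_forward(ly[[paste0("down", i, "_conv")]], cur), train)
    fc[[paste0("qd", i)]] <- qd
    cur <- lrelu_forward(qd)
  }
  rb <- resblock_forward(ly, "bott", cur, train)
  fc$bott <- rb[c("q1", "s")]
  cur <- rb$y
  for (i in rev(seq_len(d))) {
    qu <- bn_forward(ly[[paste0("up", i, "_bn")]],
                     tconv_forward(ly[[paste0("up", i, "_tconv")]], cur), train)
    fc[[paste0("qu", i)]] <- qu
    hu <- lrelu_forward(qu)
    dm <- dim(hu)
    cat_x <- c(hu, skips[[i]])
    dim(cat_x) <- c(dm[1], dm[2], dm[3], 2 * dm[4])
    qf <- bn_forward(ly[[paste0("fuse", i, "_bn")]],
                     conv_forward(ly[[paste0("fuse", i, "_conv")]], cat_x), train)
    fc[[paste0("qf", i)]] <- qf
    cur <- lrelu_forward(qf)
    rb <- resblock_forward(ly, paste0("dec", i), cur, train)
    fc[[paste0("dec", i)]] <- rb[c("q1", "s")]
    cur <- rb$y
  }
  z <- conv_forward(ly$out_conv, cur)
  # global residual: the learned correction is squashed by tanh (scaled to
  # span the full dynamic range) and added to the input, so an untouched
  # region passes through exactly; the sum is clipped to [-1, 1]
  t <- tanh(z)
  pre <- x + 2 * t
  y <- pmin(pmax(pre, -1), 1)
  fc$t <- t
  fc$in_range <- abs(pre) < 1
  g$fc <- fc
  y
}

gen_backward <- function(g, dy) {
  ly <- g$layers
  fc <- g$fc
  d <- g$spec$depth
  dpre <- dy * fc$in_range
  dz <- dpre * 2 * (1 - fc$t^2)
  dcur <- conv_backward(ly$out_conv, dz)
  dskips <- list()
  for (i in seq_len(d)) {
    dhf <- resblock_backward(ly, paste0("dec", i), fc[[paste0("dec", i)]], dcur)
    dqf <- lrelu_backward(dhf, fc[[paste0("qf", i)]])
    dcat <- conv_backward(ly[[paste0("fuse", i, "_conv")]],
                          bn_backward(ly[[paste0("fuse", i, "_bn")]], dqf))
    ci <- dim(dcat)[4] / 2
    dhu <- dcat[, , , seq_len(ci), drop = FALSE]
    dskips[[i]] <- dcat[, , , ci + seq_len(ci), drop = FALSE]
    dqu <- lrelu_backward(dhu, fc[[paste0("qu", i)]])
    dcur <- tconv_backward(ly[[paste0("up", i, "_tconv")]],
                           bn_backward(ly[[paste0("up", i, "_bn")]], dqu))
  }
  dcur <- resblock_backward(ly, "bott", fc$bott, dcur)
  for (i in rev(seq_len(d))) {
    dqd <- lrelu_backward(dcur, fc[[paste0("qd", i)]])
    dr <- conv_backward(ly[[paste0("down", i, "_conv")]],
                        bn_backward(ly[[paste0("down", i, "_bn")]], dqd))
    dr <- dr + dskips[[i]]
    dcur <- if (i > 1) {
      resblock_backward(ly, paste0("enc", i), fc[[paste0("enc", i)]], dr)
    } else dr
  }
  dq0 <- lrelu_backward(dcur, fc$q0)
  dx_stem <- conv_backward(ly$stem_conv, bn_backward(ly$stem_bn, dq0))
  if (is.null(dx_stem)) return(NULL)
  dx_stem + dpre # identity path of the global residual
}

#' Build the patch discriminator
#'
#' Deterministic normal(0, 0.02) initialization from `seed`. The model maps a
#' (source, candidate) pair of grids to per-patch sigmoid scores in (0, 1)
#' and their average.
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer initialization seed.
#' @return An object of class `gan_discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1) {
  stopifnot(inherits(spec, "discriminator_spec"))
  dnet <- new.env(parent = emptyenv())
  dnet$spec <- spec
  nl <- length(spec$channels)
  with_seed(seed, {
    ly <- list()
    cin <- spec$in_channels
    for (i in seq_len(nl)) {
      ly[[paste0("conv", i)]] <- new_conv(spec$kernel, cin, spec$channels[i],
                                          stride = spec$strides[i], pad = 1,
                                          bias = i == 1 || i == nl)
      if (i > 1 && i < nl) ly[[paste0("bn", i)]] <- new_bn(spec$channels[i])
      cin <- spec$channels[i]
    }
    dnet$layers <- ly
  })
  class(dnet) <- "gan_discriminator"
  dnet
}

#' @export
print.gan_discriminator <- function(x, ...) {
  cat(sprintf("gan_discriminator: patch discriminator, channels %s, receptive field %d px, %d parameters\n",
              paste(x$spec$channels, collapse = "-"), receptive_field(x$spec),
              n_params(x)))
  invisible(x)
}

# forward over the concatenated (source, candidate) pair; returns per-patch
# sigmoid scores, their pre-sigmoid values and the scalar mean score
disc_forward <- function(dnet, x, y, train = TRUE) {
  x <- as_batch(x); y <- as_batch(y)
  if (!identical(dim(x), dim(y))) {
    stop("source and candidate shapes differ", call. = FALSE)
  }
  dm <- dim(x)
  cur <- array(c(x, y), c(dm[1], dm[2], dm[3], 2 * dm[4]))
  ly <- dnet$layers
  nl <- length(dnet$spec$channels)
  fc <- list()
  for (i in seq_len(nl)) {
    cur <- conv_forward(ly[[paste0("conv", i)]], cur)
    if (i < nl) {
      if (i > 1) cur <- bn_forward(ly[[paste0("bn", i)]], cur, train)
      fc[[paste0("pre", i)]] <- cur
      cur <- lrelu_forward(cur)
    }
  }
  scores <- 1 / (1 + exp(-cur))
  fc$scores <- scores
  dnet$fc <- fc
  list(scores = scores, pre = cur, mean_score = mean(scores))
}

# backward from the gradient w.r.t. the pre-sigmoid patch outputs; returns the
# gradient w.r.t. the stacked 2-channel input
disc_backward <- function(dnet, dpre) {
  ly <- dnet$layers
  nl <- length(dnet$spec$channels)
  dcur <- dpre
  for (i in rev(seq_len(nl))) {
    if (i < nl) {
      dcur <- lrelu_backward(dcur, dnet$fc[[paste0("pre", i)]])
      if (i > 1) dcur <- bn_backward(ly[[paste0("bn", i)]], dcur)
    }
    dcur <- conv_backward(ly[[paste0("conv", i)]], dcur)
  }
  dcur
}

#' Loss configuration for the adversarial objective
#'
#' @param lambda_l1 Weight of the L1 reconstruction term (default 10).
#' @param adversarial Generator adversarial form: the non-saturating
#'   `-log D` (default) or the original minimax `log(1 - D)`.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_l1 = 10,
                        adversarial = c("non-saturating", "minimax")) {
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0", call. = FALSE)
  structure(list(lambda_l1 = lambda_l1,
                 adversarial = match.arg(adversarial)),
            class = "loss_config")
}

#' Adversarial binary cross-entropy losses
#'
#' From per-patch discriminator scores on real and generated pairs:
#' `loss_D = -mean(log d_real) - mean(log(1 - d_fake))` and the
#' generator adversarial term `adv_loss_G = -mean(log d_fake)`
#' (non-saturating form; the minimax form `mean(log(1 - d_fake))` is
#' available via `form`). Scores are clipped to `[eps, 1 - eps]`.
#'
#' @param d_real,d_fake Patch scores in (0, 1) (any shape).
#' @param form Generator adversarial form.
#' @param eps Clipping constant (default 1e-7).
#' @return List with `loss_D` and `adv_loss_G`.
#' @export
adversarial_losses <- function(d_real, d_fake,
                               form = c("non-saturating", "minimax"),
                               eps = 1e-7) {
  form <- match.arg(form)
  dr <- pmin(pmax(as.numeric(d_real), eps), 1 - eps)
  df <- pmin(pmax(as.numeric(d_fake), eps), 1 - eps)
  adv <- if (form == "non-saturating") -mean(log(df)) else mean(log(1 - df))
  list(loss_D = -mean(log(dr)) - mean(log(1 - df)), adv_loss_G = adv)
}

#' Mean absolute (L1) reconstruction loss
#'
#' @param generated,reference Grids of identical shape.
#' @return Mean absolute difference over all elements.
#' @export
l1_loss <- function(generated, reference) {
  if (!identical(dim(generated) %||% length(generated),
                 dim(reference) %||% length(reference))) {
    stop("generated and reference must have identical shape", call. = FALSE)
  }
  mean(abs(generated - reference))
}

#' Combined generator objective
#'
#' `adv_loss_G + lambda_l1 * l1`: the adversarial term pushes generated
#' patches toward the discriminator's notion of real, while the weighted L1
#' term anchors them to the reference.
#'
#' @param adv_loss_G Adversarial generator loss.
#' @param l1 L1 reconstruction loss.
#' @param cfg A [loss_config()].
#' @return Scalar objective.
#' @export
generator_objective <- function(adv_loss_G, l1, cfg = loss_config()) {
  if (!is.finite(adv_loss_G) || !is.finite(l1)) {
    stop("loss components must be finite", call. = FALSE)
  }
  adv_loss_G + cfg$lambda_l1 * l1
}

# checkpoint-friendly snapshots ----------------------------------------------

model_state <- function(model) {
  list(spec = model$spec, state = layers_state(model$layers))
}

model_from_state <- function(st, kind = c("generator", "discriminator")) {
  kind <- match.arg(kind)
  model <- if (kind == "generator") build_generator(st$spec, seed = 0) else
    build_discriminator(st$spec, seed = 0)
  layers_load_state(model$layers, st$state)
  model
}
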