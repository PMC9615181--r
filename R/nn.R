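# Minimal convolutional-network engine used by the generator and
# discriminator. Batches are 4D arrays with dim (H, W, N, C); convolutions are
# im2col gathers feeding BLAS matrix products, and every layer carries its own
# exact backward pass (finite-difference checked in the test suite). Layers
# are environments so parameters, gradients and optimizer state can be
# updated in place during training.

# `bias = FALSE` for convolutions immediately followed by batch
# normalization, whose shift parameter absorbs it
new_conv <- function(k, cin, cout, stride = 1, pad = (k - 1) %/% 2,
                     init_sd = 0.02, bias = TRUE) {
  L <- new.env(parent = emptyenv())
  L$type <- "conv"; L$k <- k; L$cin <- cin; L$cout <- cout
  L$stride <- stride; L$pad <- pad; L$bias <- bias
  L$W <- array(rnorm(k * k * cin * cout, sd = init_sd), c(k, k, cin, cout))
  if (bias) L$b <- numeric(cout)
  L
}

new_tconv <- function(k, cin, cout, stride = 2, pad = 1, init_sd = 0.02,
                      bias = TRUE) {
  L <- new.env(parent = emptyenv())
  L$type <- "tconv"; L$k <- k; L$cin <- cin; L$cout <- cout
  L$stride <- stride; L$pad <- pad; L$bias <- bias
  L$W <- array(rnorm(k * k * cin * cout, sd = init_sd), c(k, k, cin, cout))
  if (bias) L$b <- numeric(cout)
  L
}

new_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  L <- new.env(parent = emptyenv())
  L$type <- "bn"; L$c <- c; L$eps <- eps; L$momentum <- momentum
  L$gamma <- rep(1, c); L$beta <- numeric(c)
  L$rmean <- numeric(c); L$rvar <- rep(1, c)
  L
}

# cross-correlation forward; caches the im2col matrix for the weight gradient
conv_forward <- function(L, x) {
  d <- dim(x)
  stopifnot(d[4] == L$cin)
  k <- L$k; s <- L$stride; p <- L$pad
  ho <- (d[1] + 2 * p - k) / s + 1; wo <- (d[2] + 2 * p - k) / s + 1
  if (ho != floor(ho) || wo != floor(wo) || ho < 1 || wo < 1) {
    stop(sprintf("conv: input %dx%d incompatible with kernel %d stride %d pad %d",
                 d[1], d[2], k, s, p), call. = FALSE)
  }
  colm <- if (k == 1 && s == 1 && p == 0) {
    dim(x) <- c(prod(d[1:3]), d[4])
    x
  } else {
    rows <- ho * wo * d[3]
    if (is.null(L$colbuf) || nrow(L$colbuf) != rows) {
      L$colbuf <- matrix(0, rows, k * k * L$cin)
    }
    cpp_im2col_into(L$colbuf, x, as.integer(d), k, s, p)
    L$colbuf
  }
  y <- colm %*% matrix(L$W, ncol = L$cout)
  if (L$bias) y <- y + rep(L$b, each = nrow(y))
  L$cache <- list(colm = colm, in_dim = d, ho = ho, wo = wo)
  dim(y) <- c(ho, wo, d[3], L$cout)
  y
}

conv_backward <- function(L, dy) {
  cc <- L$cache
  dim(dy) <- c(length(dy) / L$cout, L$cout)
  L$dW <- array(crossprod(cc$colm, dy), dim(L$W))
  if (L$bias) L$db <- colSums(dy)
  if (isTRUE(L$input_layer)) return(NULL) # input gradient unused
  dcol <- dy %*% t(matrix(L$W, ncol = L$cout))
  if (L$k == 1 && L$stride == 1 && L$pad == 0) {
    dim(dcol) <- cc$in_dim
    dcol
  } else {
    cpp_col2im(dcol, as.integer(cc$in_dim), L$k, L$stride, L$pad)
  }
}

# zero-stuffing turns a stride-s transposed convolution into a stride-1
# convolution with a spatially flipped kernel
stuff_hw <- function(x, s) {
  if (s == 1) return(x)
  d <- dim(x)
  out <- array(0, c((d[1] - 1) * s + 1, (d[2] - 1) * s + 1, d[3], d[4]))
  out[1 + s * (0:(d[1] - 1)), 1 + s * (0:(d[2] - 1)), , ] <- x
  out
}

flip_k <- function(W) W[dim(W)[1]:1, dim(W)[2]:1, , , drop = FALSE]

tconv_forward <- function(L, x) {
  d <- dim(x)
  stopifnot(d[4] == L$cin)
  if (L$k == L$stride && L$pad == 0) {
    # non-overlapping upsampling: one GEMM plus an index scatter
    xm <- x
    dim(xm) <- c(prod(d[1:3]), d[4])
    wm <- aperm(L$W, c(3, 1, 2, 4))
    dim(wm) <- c(L$cin, L$k * L$k * L$cout)
    y <- cpp_tconv_scatter(xm %*% wm, as.integer(d), L$k, L$cout)
    if (L$bias) y <- y + rep(L$b, each = length(y) / L$cout)
    L$cache <- list(xm = xm, in_dim = d, direct = TRUE)
    return(y)
  }
  xs <- stuff_hw(x, L$stride)
  inner <- new_conv(L$k, L$cin, L$cout, stride = 1, pad = L$k - 1 - L$pad,
                    bias = L$bias)
  inner$W <- flip_k(L$W)
  if (L$bias) inner$b <- L$b
  y <- conv_forward(inner, xs)
  L$cache <- list(inner = inner, in_dim = d, direct = FALSE)
  y
}

tconv_backward <- function(L, dy) {
  if (L$cache$direct) {
    d <- L$cache$in_dim
    dym <- cpp_tconv_gather(dy, as.integer(dim(dy)), L$k)
    dwm <- crossprod(L$cache$xm, dym)
    dim(dwm) <- c(L$cin, L$k, L$k, L$cout)
    L$dW <- aperm(dwm, c(2, 3, 1, 4))
    if (L$bias) {
      dyc <- dy
      dim(dyc) <- c(length(dy) / L$cout, L$cout)
      L$db <- colSums(dyc)
    }
    wm <- aperm(L$W, c(3, 1, 2, 4))
    dim(wm) <- c(L$cin, L$k * L$k * L$cout)
    dx <- dym %*% t(wm)
    dim(dx) <- d
    return(dx)
  }
  inner <- L$cache$inner
  dxs <- conv_backward(inner, dy)
  L$dW <- flip_k(inner$dW)
  if (L$bias) L$db <- inner$db
  d <- L$cache$in_dim; s <- L$stride
  dxs[1 + s * (0:(d[1] - 1)), 1 + s * (0:(d[2] - 1)), , , drop = FALSE]
}

bn_forward <- function(L, x, train) {
  d <- dim(x)
  m <- prod(d[1:3])
  if (train) {
    st <- cpp_bn_stats(x, d[4])
    mu <- st$mu; va <- st$va
    L$rmean <- (1 - L$momentum) * L$rmean + L$momentum * mu
    L$rvar <- (1 - L$momentum) * L$rvar + L$momentum * va
  } else {
    mu <- L$rmean; va <- L$rvar
  }
  ivstd <- 1 / sqrt(va + L$eps)
  ap <- cpp_bn_apply(x, d[4], mu, ivstd, L$gamma, L$beta)
  y <- ap$y
  L$cache <- list(xhat = ap$xhat, ivstd = ivstd, m = m, train = train, dims = d)
  dim(y) <- d
  y
}

bn_backward <- function(L, dy) {
  cc <- L$cache
  r <- cpp_bn_backward(dy, cc$xhat, cc$ivstd, L$gamma, cc$dims[4], cc$train)
  L$dgamma <- r$dgamma
  L$dbeta <- r$dbeta
  dx <- r$dx
  dim(dx) <- cc$dims
  dx
}

lrelu_forward <- function(x, a = 0.2) cpp_lrelu(x, a)
lrelu_backward <- function(dy, x, a = 0.2) cpp_lrelu_grad(dy, x, a)

# parameter bookkeeping -------------------------------------------------------

layer_param_names <- function(L) {
  switch(L$type,
         conv = ,
         tconv = if (L$bias) c("W", "b") else "W",
         bn = c("gamma", "beta"))
}

n_params_layers <- function(layers) {
  sum(vapply(layers, function(L) {
    sum(vapply(layer_param_names(L), function(nm) length(L[[nm]]), numeric(1)))
  }, numeric(1)))
}

layers_state <- function(layers) {
  lapply(layers, function(L) {
    st <- lapply(layer_param_names(L), function(nm) L[[nm]])
    names(st) <- layer_param_names(L)
    if (L$type == "bn") { st$rmean <- L$rmean; st$rvar <- L$rvar }
    st
  })
}

layers_load_state <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (nm in names(state[[i]])) layers[[i]][[nm]] <- state[[i]][[nm]]
  }
  invisible(layers)
}

# Adam ------------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(L) {
    nms <- layer_param_names(L)
    st <- lapply(nms, function(nm) {
      list(m = array(0, dim(L[[nm]]) %||% length(L[[nm]])),
           v = array(0, dim(L[[nm]]) %||% length(L[[nm]])))
    })
    names(st) <- nms
    st
  })
}

adam_step <- function(layers, opt, lr, beta1, beta2, t, eps = 1e-8) {
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    for (nm in layer_param_names(L)) {
      g <- switch(nm, W = L$dW, b = L$db, gamma = L$dgamma, beta = L$dbeta)
      if (is.null(g)) next
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      opt[[i]][[nm]] <- st
      L[[nm]] <- L[[nm]] - lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    }
  }
  opt
}

# gradient accumulation across two backward passes (real/fake discriminator
# batches): snapshot after the first, add back after the second
grad_snapshot <- function(layers) {
  lapply(layers, function(L) {
    g <- list(W = L$dW, b = L$db, gamma = L$dgamma, beta = L$dbeta)
    g[!vapply(g, is.null, logical(1))]
  })
}

grad_accumulate <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (nm in names(snap[[i]])) {
      fld <- paste0("d", nm)
      layers[[i]][[fld]] <- layers[[i]][[fld]] + snap[[i]][[nm]]
    }
  }
  invisible(layers)
}
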