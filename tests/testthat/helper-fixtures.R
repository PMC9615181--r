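# Shared fixtures built in code: noise-free phantom settings, rasterized
# shapes, and a finite-difference gradient checker for the network layers.

noise_free_params <- function(...) {
  phantom_params(background_texture_sigma = 0, sensor_noise_sigma = 0,
                 n_distractors = 0, ...)
}

disc_mask <- function(n, center, r) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

ellipse_mask <- function(n, center, a, b, theta = 0) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  u <- (rows - center[1]) * cos(theta) + (cols - center[2]) * sin(theta)
  v <- -(rows - center[1]) * sin(theta) + (cols - center[2]) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# central-difference gradient of scalar-valued f at x (small arrays only)
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

ns <- asNamespace("cctamar")
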