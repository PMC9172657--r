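# Shared helpers: finite-difference gradients and independent brute-force
# oracles kept deliberately separate from the package's own code paths.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_img <- function(n, m = n) matrix(runif(n * m), n, m)

# plain-loop 2-D convolution reference (zero padding)
naive_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); kd <- dim(w)
  ho <- (d[1] + 2 * pad - kd[1]) %/% stride + 1L
  wo <- (d[2] + 2 * pad - kd[2]) %/% stride + 1L
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out <- array(0, c(ho, wo, kd[4]))
  for (co in seq_len(kd[4])) for (io in seq_len(ho)) for (jo in seq_len(wo)) {
    patch <- xp[(io - 1L) * stride + seq_len(kd[1]),
                (jo - 1L) * stride + seq_len(kd[2]), , drop = FALSE]
    out[io, jo, co] <- sum(patch * w[, , , co]) + b[co]
  }
  out
}

# windowed SSIM reference: explicit loop over window positions with
# Gaussian weights (population statistics), matching the package's stated
# convention but through an independent code path
naive_ssim <- function(x, y, k1 = 0.01, k2 = 0.02, L = 1,
                       size = 11L, sigma = 1.5) {
  r <- (seq_len(size) - (size + 1) / 2)
  g1 <- exp(-r^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  H <- nrow(x); n <- 0L; acc <- 0
  for (i in seq_len(H - size + 1L)) for (j in seq_len(ncol(x) - size + 1L)) {
    xs <- x[i:(i + size - 1L), j:(j + size - 1L)]
    ys <- y[i:(i + size - 1L), j:(j + size - 1L)]
    mx <- sum(W * xs); my <- sum(W * ys)
    vx <- sum(W * xs^2) - mx^2; vy <- sum(W * ys^2) - my^2
    cxy <- sum(W * xs * ys) - mx * my
    acc <- acc + ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
    n <- n + 1L
  }
  acc / n
}

# brute-force count of valid patch offsets
naive_patch_count <- function(H, W, p, s) {
  n <- 0L
  for (r in seq(0L, H, by = s)) for (cl in seq(0L, W, by = s))
    if (r + p <= H && cl + p <= W) n <- n + 1L
  n
}

micro_dataset <- function(seed = 5L, patch = 32L, n_eval = 1L,
                          noise = "gaussian") {
  build_unpaired_dataset(
    n_subjects_x = 1L, n_subjects_y = 1L, slices_per_subject = 2L,
    image_size = patch, dose = dose_model(noise_model = noise),
    patch_size = patch, stride = patch, n_eval_slices = n_eval, seed = seed)
}

micro_state <- function(seed = 1L, patch = 32L, ...) {
  train_state_init(
    train_config("tiny", seed = seed, total_steps = 20L,
                 decay_start_step = 10L, decay_end_step = 20L, ...),
    generator_config(channels = 8L, redcnn_layers = 2L, unet_stages = 2L,
                     reduction_dim = 4L, input_size = patch, residual = TRUE,
                     clamp_output = TRUE),
    discriminator_config(patch, 8L),
    loss_config(adversarial_form = "least_squares"),
    phi_width_scale = 1 / 16)
}
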